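# The study harness: named experiment specifications over (group,
# microphone) cohorts, repeated 80/20 train/test resampling with optional
# age matching, the training-size sweep, and the statistical analyses
# (normality + unpaired t-test, EER-WRR correlation, logarithmic
# training-size regression).

#' Experiment specification
#'
#' Mirrors the study's experiment table: a named cohort filter, a speaker
#' count, an 80/20 split and repeated resampling.
#'
#' @param name Experiment label, e.g. `"dysglossia-dnt-85"`.
#' @param n_speakers Speakers sampled per repetition (>= 5).
#' @param groups Optional data frame with columns `group` and `microphone`;
#'   `NULL` pools all speakers.
#' @param subset `"adults"`, `"children"` or `"mixed"`.
#' @param train_fraction Fraction of sampled speakers assigned to training
#'   (default 0.8; the rest test).
#' @param repetitions Number of independent resampling repetitions (the study
#'   protocol uses 20).
#' @param age_match Optional list `list(mean =, sd =)` the sampled cohort's
#'   age distribution is steered toward (weighted sampling).
#' @param seed Integer seed covering all repetitions.
#' @return An `experiment_spec` object.
#' @export
experiment_spec <- function(name, n_speakers, groups = NULL,
                            subset = c("mixed", "adults", "children"),
                            train_fraction = 0.8, repetitions = 20L,
                            age_match = NULL, seed = 1L) {
  subset <- match.arg(subset)
  stopifnot(n_speakers >= 5, train_fraction > 0, train_fraction < 1,
            repetitions >= 1)
  structure(list(name = name, n_speakers = as.integer(n_speakers),
                 groups = groups, subset = subset,
                 train_fraction = train_fraction,
                 repetitions = as.integer(repetitions),
                 age_match = age_match, seed = as.integer(seed)),
            class = "experiment_spec")
}

# weighted speaker sampling steering ages toward a target normal distribution
sample_speakers <- function(sp, n, age_match = NULL) {
  if (is.null(age_match)) return(sp$speaker_id[sample(nrow(sp), n)])
  w <- dnorm(sp$age, age_match$mean, age_match$sd)
  w <- w / sum(w)
  sp$speaker_id[sample(nrow(sp), n, prob = w)]
}

filter_speakers <- function(manifest, spec) {
  sp <- speaker_table(manifest)
  if (spec$subset == "adults") sp <- sp[sp$age > 20, , drop = FALSE]
  if (spec$subset == "children")
    sp <- sp[sp$age >= 2 & sp$age <= 20, , drop = FALSE]
  if (!is.null(spec$groups)) {
    keys <- paste(spec$groups$group, spec$groups$microphone)
    sp <- sp[paste(sp$group, sp$microphone) %in% keys, , drop = FALSE]
  }
  sp
}

#' Run one verification experiment
#'
#' Per repetition: sample `n_speakers` from the matching cohort (age-weighted
#' if requested), assign 80%/20% of them to disjoint training and test sets,
#' train a GE2E encoder from scratch on the training speakers' partial
#' utterances, compute utterance d-vectors for the test speakers, score all
#' probe-vs-centroid trials, and record the EER together with the test set's
#' mean WRR. Fully seeded and reproducible.
#'
#' @param manifest A filtered [corpus_manifest()].
#' @param spec An [experiment_spec()].
#' @param features Precomputed [prepare_features()] output for `manifest`
#'   (pass it when running several experiments over one corpus); computed
#'   on the fly when `NULL`.
#' @param audio_dir Needed only when `features` is `NULL`.
#' @param encoder_cfg,train_cfg,eval_cfg,frontend_cfg Stage configurations.
#' @return An `experiment_result`: the spec plus per-repetition `eers`,
#'   `wrrs`, `thresholds`, and `mean_eer` / `sd_eer` in percent.
#' @export
run_experiment <- function(manifest, spec, features = NULL, audio_dir = NULL,
                           encoder_cfg = encoder_config(),
                           train_cfg = train_config(),
                           eval_cfg = eval_config(),
                           frontend_cfg = frontend_config()) {
  stopifnot(inherits(spec, "experiment_spec"))
  sp <- filter_speakers(manifest, spec)
  if (nrow(sp) < spec$n_speakers)
    stop("experiment '", spec$name, "' needs ", spec$n_speakers,
         " speakers but only ", nrow(sp), " match the cohort filter")
  if (is.null(features)) {
    if (is.null(audio_dir)) stop("either features or audio_dir is required")
    features <- prepare_features(manifest, audio_dir, frontend_cfg)
  }
  wrr_by_speaker <- stats::setNames(sp$wrr, sp$speaker_id)
  n_test <- max(2L, as.integer(round((1 - spec$train_fraction) *
                                       spec$n_speakers)))
  eers <- numeric(spec$repetitions)
  wrrs <- numeric(spec$repetitions)
  thresholds <- numeric(spec$repetitions)
  withr::with_seed(spec$seed, {
    for (rep in seq_len(spec$repetitions)) {
      chosen <- sample_speakers(sp, spec$n_speakers, spec$age_match)
      test_ids <- sample(chosen, n_test)
      train_ids <- setdiff(chosen, test_ids)
      tc <- train_cfg
      tc$seed <- sample.int(2147483646, 1)
      tc$N <- min(tc$N, length(train_ids))
      enc <- ge2e_train(features$partials[train_ids], encoder_cfg, tc)
      dvecs <- lapply(features$utterances[test_ids], function(utts) {
        do.call(rbind, lapply(utts, function(f)
          utterance_dvector(enc, f, eval_cfg)))
      })
      trials <- build_trials(dvecs, eval_cfg)
      res <- compute_eer(trials)
      eers[rep] <- res$eer
      thresholds[rep] <- res$threshold
      wrrs[rep] <- mean(wrr_by_speaker[test_ids])
    }
  })
  structure(list(spec = spec, eers = eers, wrrs = wrrs,
                 thresholds = thresholds,
                 mean_eer = mean(eers), sd_eer = sd(eers)),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %s: EER %.2f +/- %.2f %% (%d repetitions)\n",
              x$spec$name, x$mean_eer,
              ifelse(is.na(x$sd_eer), 0, x$sd_eer), length(x$eers)))
  invisible(x)
}

#' Training-size sweep
#'
#' Runs one experiment per speaker count, each drawing from the pooled
#' manifest with the standard 80/20 split, to trace how EER falls as the
#' number of training speakers grows.
#'
#' @param manifest A filtered [corpus_manifest()].
#' @param sizes Integer vector of total speaker counts (e.g. the study used
#'   50, 500, 1500, 3000; desk-scale corpora use smaller sizes).
#' @param features,audio_dir,encoder_cfg,train_cfg,eval_cfg,frontend_cfg As
#'   in [run_experiment()].
#' @param repetitions,seed Passed to each size's [experiment_spec()].
#' @return A list of `experiment_result`s, one per size (empty for empty
#'   `sizes`).
#' @export
training_size_sweep <- function(manifest, sizes, features = NULL,
                                audio_dir = NULL,
                                encoder_cfg = encoder_config(),
                                train_cfg = train_config(),
                                eval_cfg = eval_config(),
                                frontend_cfg = frontend_config(),
                                repetitions = 20L, seed = 1L) {
  out <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    spec <- experiment_spec(name = sprintf("all-spk-%d", sizes[i]),
                            n_speakers = sizes[i], groups = NULL,
                            repetitions = repetitions,
                            seed = seed + i - 1L)
    out[[i]] <- run_experiment(manifest, spec, features, audio_dir,
                               encoder_cfg, train_cfg, eval_cfg, frontend_cfg)
  }
  out
}

#' Compare two groups of EER values
#'
#' Shapiro-Wilk normality check on each group followed by a two-tailed
#' unpaired t-test (pooled-variance Student's t by default, Welch optional).
#' Significance is declared at P <= 0.05.
#'
#' @param a,b Numeric vectors of EER values (length >= 3).
#' @param welch Use Welch's unequal-variance t-test instead of the pooled
#'   test.
#' @return A list with `t`, `p`, `significant`, and `normality` (per-group
#'   Shapiro-Wilk `W` and p-values; `NA` for constant input).
#' @export
compare_groups <- function(a, b, welch = FALSE) {
  stopifnot(length(a) >= 3, length(b) >= 3)
  sw <- function(x) {
    out <- tryCatch(shapiro.test(x), error = function(e) NULL)
    if (is.null(out)) c(W = NA_real_, p = NA_real_)
    else c(W = unname(out$statistic), p = out$p.value)
  }
  na <- sw(a)
  nb <- sw(b)
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) {
      t_stat <- 0; p <- 1
    } else {
      t_stat <- sign(mean(a) - mean(b)) * Inf; p <- 0
    }
  } else {
    tt <- t.test(a, b, var.equal = !welch, alternative = "two.sided")
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  list(t = t_stat, p = p, significant = p <= 0.05,
       normality = list(W_a = na[["W"]], p_a = na[["p"]],
                        W_b = nb[["W"]], p_b = nb[["p"]]))
}

#' Correlation between EER and intelligibility (WRR)
#'
#' Pearson correlation between an experiment's per-repetition EERs and the
#' mean WRR of each repetition's test set.
#'
#' @param result An `experiment_result` (or a list with `eers` and `wrrs`).
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
correlate_eer_wrr <- function(result) {
  e <- result$eers
  w <- result$wrrs
  stopifnot(length(e) == length(w), length(e) >= 3)
  if (var(e) == 0 || var(w) == 0)
    stop("EER-WRR correlation undefined: zero variance in one of the series")
  cor(e, w)
}

#' Logarithmic least-squares regression of EER on training size
#'
#' Ordinary least squares of `y = a + b * ln(x)`, the model describing the
#' logarithmic improvement of verification performance with the number of
#' training speakers.
#'
#' @param x Speaker counts (> 0).
#' @param y EER values in percent.
#' @return A `regression_fit` list with `intercept_a`, `slope_b` and
#'   `r_squared`.
#' @export
fit_log_regression <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2, all(x > 0))
  if (length(unique(x)) < 2)
    stop("all speaker counts equal: singular design")
  fit <- lm(y ~ log(x))
  structure(list(intercept_a = unname(coef(fit)[1]),
                 slope_b = unname(coef(fit)[2]),
                 r_squared = summary(fit)$r.squared),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> y = %.6f %+.6f * ln(x), R^2 = %.4f\n",
              x$intercept_a, x$slope_b, x$r_squared))
  invisible(x)
}
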