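# Corpus manifest data model, exclusion filters and CSV round-trip.
#
# A manifest is a plain data frame with one row per utterance; speaker-level
# attributes are repeated on each of the speaker's rows. Columns:
#   speaker_id, utterance_id, wav_path, age, sex, group, microphone, wrr,
#   quality_flag, duration_s, diagnosis_present, environment_present
# wav_path is stored relative to the corpus audio directory.

PATHOLOGY_GROUPS <- c("dysglossia", "dysarthria", "dysphonia", "CLP", "control")
MICROPHONES <- c("dnt", "plant", "logi")
QUALITY_FLAGS <- c("ok", "noisy", "test", "multi_speaker")

#' Construct and validate a corpus manifest
#'
#' @param df Data frame with one row per utterance (see Details).
#' @param subset_label One of `"adults"`, `"children"`, `"mixed"`.
#' @details Required columns: `speaker_id`, `utterance_id`, `wav_path`, `age`,
#'   `sex`, `group`, `microphone`, `wrr`, `quality_flag`, `duration_s`.
#'   Optional logical columns `diagnosis_present` and `environment_present`
#'   default to `TRUE`; they carry whether a diagnosis and a recording
#'   environment are on record for the speaker, which the exclusion filters
#'   check. `age` and `wrr` may be `NA` (missing metadata).
#' @return The validated manifest (class `corpus_manifest`).
#' @export
corpus_manifest <- function(df, subset_label = c("mixed", "adults", "children")) {
  subset_label <- match.arg(subset_label)
  required <- c("speaker_id", "utterance_id", "wav_path", "age", "sex",
                "group", "microphone", "wrr", "quality_flag", "duration_s")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "))
  if (!"diagnosis_present" %in% names(df)) df$diagnosis_present <- TRUE
  if (!"environment_present" %in% names(df)) df$environment_present <- TRUE
  bad_group <- !is.na(df$group) & !df$group %in% PATHOLOGY_GROUPS
  if (any(bad_group))
    stop("unknown pathology group(s): ",
         paste(unique(df$group[bad_group]), collapse = ", "))
  bad_flag <- !df$quality_flag %in% QUALITY_FLAGS
  if (any(bad_flag))
    stop("unknown quality flag(s): ",
         paste(unique(df$quality_flag[bad_flag]), collapse = ", "))
  if (any(!is.na(df$duration_s) & df$duration_s <= 0))
    stop("utterance durations must be positive")
  if (any(!is.na(df$wrr) & (df$wrr < 0 | df$wrr > 100)))
    stop("WRR must lie in [0, 100]")
  if (anyDuplicated(df$utterance_id))
    stop("utterance_id values must be unique")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  attr(df, "subset_label") <- subset_label
  class(df) <- c("corpus_manifest", "data.frame")
  df
}

#' @export
print.corpus_manifest <- function(x, ...) {
  cat(sprintf("<corpus_manifest> %d speakers, %d utterances (%s subset)\n",
              length(unique(x$speaker_id)), nrow(x),
              attr(x, "subset_label") %||% "mixed"))
  if (nrow(x) > 0) {
    tab <- table(x$group[!duplicated(x$speaker_id)])
    cat("  speakers by group:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_manifest <- function(df, subset_label = "mixed") {
  # internal: re-wrap rows already known to be valid
  rownames(df) <- NULL
  attr(df, "subset_label") <- subset_label
  class(df) <- c("corpus_manifest", "data.frame")
  df
}

#' Apply the corpus exclusion filters
#'
#' Reproduces the corpus curation rules: speakers missing any of WRR,
#' diagnosis, age, microphone or recording environment are purged; utterances
#' flagged `noisy`, `test` or `multi_speaker` are dropped; speakers left with
#' fewer than `min_utterances` utterances after those drops are excluded. The
#' minimum-utterance rule is counted after the utterance-level exclusions.
#' Row order of surviving records is preserved, and the operation is
#' idempotent.
#'
#' @param manifest A [corpus_manifest()].
#' @param min_utterances Minimum retained utterances per speaker (default 8).
#' @return The filtered manifest; an empty manifest (zero rows) if nothing
#'   survives or the input is empty.
#' @export
apply_exclusion_filters <- function(manifest, min_utterances = 8L) {
  stopifnot(inherits(manifest, "corpus_manifest"))
  if (nrow(manifest) == 0) return(manifest)
  m <- manifest
  # (i) complete speaker metadata
  meta_ok <- !is.na(m$wrr) & !is.na(m$age) &
    !is.na(m$microphone) & m$microphone %in% MICROPHONES &
    !is.na(m$diagnosis_present) & m$diagnosis_present &
    !is.na(m$environment_present) & m$environment_present
  # (ii)-(iv) utterance-level quality: only 'ok' survives
  utt_ok <- m$quality_flag == "ok"
  m <- m[meta_ok & utt_ok, , drop = FALSE]
  # (v) minimum utterance count after the drops above
  counts <- table(m$speaker_id)
  keep <- names(counts)[counts >= min_utterances]
  m <- m[m$speaker_id %in% keep, , drop = FALSE]
  as_manifest(m, attr(manifest, "subset_label") %||% "mixed")
}

#' Split a manifest into adult and child subsets
#'
#' Adults are speakers older than 20 years; children span 2 to 20 years
#' inclusive (a speaker aged exactly 20 is a child). Speakers younger than 2
#' are dropped; the two subsets are disjoint.
#'
#' @param manifest A [corpus_manifest()] with no missing ages.
#' @return A list with manifests `adults` and `children`.
#' @export
split_by_age <- function(manifest) {
  stopifnot(inherits(manifest, "corpus_manifest"))
  if (any(is.na(manifest$age)))
    stop("all speakers must have an age; run apply_exclusion_filters first")
  if (any(manifest$age < 0)) stop("negative ages are invalid")
  adults <- manifest[manifest$age > 20, , drop = FALSE]
  children <- manifest[manifest$age >= 2 & manifest$age <= 20, , drop = FALSE]
  list(adults = as_manifest(adults, "adults"),
       children = as_manifest(children, "children"))
}

#' Write a manifest to CSV
#'
#' @param manifest A [corpus_manifest()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "corpus_manifest"))
  df <- as.data.frame(manifest)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a manifest from CSV
#'
#' @param path CSV path written by [write_manifest()].
#' @param subset_label Subset label to attach (default `"mixed"`).
#' @return A [corpus_manifest()].
#' @export
read_manifest <- function(path, subset_label = "mixed") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$speaker_id <- as.character(df$speaker_id)
  df$utterance_id <- as.character(df$utterance_id)
  corpus_manifest(df, subset_label)
}

# Speaker-level view of a manifest (one row per speaker).
speaker_table <- function(manifest) {
  sp <- manifest[!duplicated(manifest$speaker_id),
                 c("speaker_id", "age", "sex", "group", "microphone", "wrr"),
                 drop = FALSE]
  rownames(sp) <- NULL
  sp
}
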