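#' The artifact label vocabulary
#'
#' Thirteen codes: 0 is background (non-artifact) EEG and 1–12 are artifact
#' classes, following the TUH artifact-corpus naming where a short code
#' exists. The synthetic generator uses `musc`, `eyem`, `elpp` and `chew`.
#'
#' @return A tibble with columns `code` (integer 0–12) and `label`.
#' @export
artifact_vocabulary <- function() {
  tibble::tibble(
    code = 0:12,
    label = c("bckg", "musc", "eyem", "elpp", "chew", "shiv", "elec",
              "eyem_musc", "musc_elec", "eyem_chew", "eyem_shiv",
              "eyem_elec", "chew_musc")
  )
}

#' Construct a label track
#'
#' A label track is an ordered set of half-open time intervals
#' `[start_s, end_s)` with class labels, each bound either to a single channel
#' (artifacts; 0-based `channel` index) or global (`channel = NA`, used for
#' seizures). Times are seconds from recording start.
#'
#' @param entries a data frame with columns `start_s`, `end_s`, `label`
#'   (character) and `channel` (integer, `NA` for global). A zero-row frame
#'   gives an empty track.
#' @param vocabulary a tibble of `code`/`label` pairs; must contain code 0.
#'   Defaults to `"seizure"` tracks (`bckg` = 0, `seizure` = 1) when every
#'   label is `"seizure"`, else [artifact_vocabulary()].
#' @param record_id record identity string.
#' @return An object of class `eeg_labels`; `entries` sorted by `start_s`.
#' @examples
#' label_track(data.frame(start_s = 10, end_s = 72.5,
#'                        label = "seizure", channel = NA))
#' @export
label_track <- function(entries, vocabulary = NULL, record_id = "rec") {
  entries <- tibble::as_tibble(entries)
  if (nrow(entries) == 0) {
    entries <- tibble::tibble(start_s = numeric(), end_s = numeric(),
                              label = character(), channel = integer())
  }
  stopifnot(all(c("start_s", "end_s", "label", "channel") %in% names(entries)))
  entries$start_s <- as.numeric(entries$start_s)
  entries$end_s <- as.numeric(entries$end_s)
  entries$label <- as.character(entries$label)
  entries$channel <- as.integer(entries$channel)
  if (any(entries$start_s < 0) || any(entries$end_s <= entries$start_s)) {
    stop("label intervals must satisfy 0 <= start_s < end_s", call. = FALSE)
  }
  if (is.null(vocabulary)) {
    vocabulary <- if (nrow(entries) == 0 || all(entries$label %in% c("seizure", "bckg"))) {
      tibble::tibble(code = 0:1, label = c("bckg", "seizure"))
    } else {
      artifact_vocabulary()
    }
  }
  vocabulary <- tibble::as_tibble(vocabulary)
  stopifnot(all(c("code", "label") %in% names(vocabulary)))
  if (!0 %in% vocabulary$code) {
    stop("vocabulary must contain code 0 (background)", call. = FALSE)
  }
  unknown <- setdiff(entries$label, vocabulary$label)
  if (length(unknown) > 0) {
    stop("labels not in vocabulary: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  # conflicting overlap check: same channel (or both global), different labels
  e <- entries[order(entries$start_s), ]
  if (nrow(e) > 1) {
    for (i in seq_len(nrow(e) - 1)) {
      j <- which(e$start_s[(i + 1):nrow(e)] < e$end_s[i]) + i
      for (k in j) {
        same_ch <- (is.na(e$channel[i]) && is.na(e$channel[k])) ||
          (!is.na(e$channel[i]) && !is.na(e$channel[k]) &&
             e$channel[i] == e$channel[k])
        if (same_ch && e$label[i] != e$label[k]) {
          stop(sprintf(
            "conflicting overlapping labels '%s'/'%s' on the same channel at %.3f s",
            e$label[i], e$label[k], e$start_s[k]), call. = FALSE)
        }
      }
    }
  }
  structure(list(entries = e, vocabulary = vocabulary,
                 record_id = as.character(record_id)),
            class = "eeg_labels")
}

#' @export
print.eeg_labels <- function(x, ...) {
  cat(sprintf("<eeg_labels> %s: %d interval(s)\n", x$record_id, nrow(x$entries)))
  if (nrow(x$entries) > 0) print(x$entries, n = 10)
  invisible(x)
}

#' Read / write annotation CSV
#'
#' The on-disk interchange for both seizure and artifact annotations is a CSV
#' with header `start_s,end_s,label,channel`, where `channel` is a 0-based
#' integer or the literal `global`, and times are seconds from recording
#' start (half-open intervals).
#'
#' @param path CSV path.
#' @param vocabulary,record_id passed to [label_track()].
#' @return `read_annotations()` returns an `eeg_labels`;
#'   `write_annotations()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("start_s,end_s,label,channel", "10.0,72.5,seizure,global"), f)
#' read_annotations(f)
#' @export
read_annotations <- function(path, vocabulary = NULL, record_id = NULL) {
  if (!file.exists(path)) stop("cannot read annotations: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("numeric", "numeric", "character", "character"))
  if (!identical(names(df), c("start_s", "end_s", "label", "channel"))) {
    stop("annotation CSV must have header start_s,end_s,label,channel",
         call. = FALSE)
  }
  ch <- suppressWarnings(as.integer(df$channel))
  bad <- !(tolower(df$channel) == "global" | !is.na(ch))
  if (any(bad)) {
    stop("channel must be a 0-based integer or 'global'", call. = FALSE)
  }
  df$channel <- ifelse(tolower(df$channel) == "global", NA_integer_, ch)
  if (is.null(record_id)) record_id <- sub("\\.[^.]*$", "", basename(path))
  label_track(df, vocabulary, record_id)
}

#' @param track an `eeg_labels` object.
#' @rdname read_annotations
#' @export
write_annotations <- function(track, path) {
  stopifnot(inherits(track, "eeg_labels"))
  e <- track$entries
  out <- data.frame(
    start_s = e$start_s, end_s = e$end_s, label = e$label,
    channel = ifelse(is.na(e$channel), "global", as.character(e$channel))
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# total overlap of [a0,a1) with each half-open interval row of (s,e); scalar
interval_overlap <- function(a0, a1, s, e) {
  sum(pmax(0, pmin(a1, e) - pmax(a0, s)))
}
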