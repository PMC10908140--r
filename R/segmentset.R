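#' Segment sets: fixed-length EEG segments with class labels
#'
#' A `segment_set` is the universal currency of the package: a numeric matrix
#' of `n_segments x segment_len` amplitude values (one row per 1-second EEG
#' segment) together with an integer label per row. Two labelling schemes are
#' supported: `"five_class"` (labels 1..5, the five recording conditions of
#' the epileptic-seizure recognition data: a = ictal/seizure, b = tumour
#' area, c = healthy area, d = eyes closed, e = eyes open) and `"binary"`
#' (1 = seizure, 0 = non-seizure).
#'
#' @param signals numeric matrix, one row per segment.
#' @param labels integer vector, one label per row of `signals`.
#' @param label_scheme `"five_class"` or `"binary"`.
#' @param class_names optional character vector of class names in label
#'   order; defaults to `c("a","b","c","d","e")` or
#'   `c("non_seizure","seizure")`.
#' @param sampling_rate samples per second (178 by convention).
#' @return An object of class `segment_set`.
#' @examples
#' s <- segment_set(matrix(rnorm(20), 4, 5), c(1L, 2L, 3L, 5L))
#' n_segments(s)
#' @export
segment_set <- function(signals, labels,
                        label_scheme = c("five_class", "binary"),
                        class_names = NULL, sampling_rate = 178) {
  label_scheme <- match.arg(label_scheme)
  signals <- as.matrix(signals)
  storage.mode(signals) <- "double"
  labels <- as.integer(labels)
  if (nrow(signals) != length(labels)) {
    stop("n_segments mismatch: ", nrow(signals), " signal rows but ",
         length(labels), " labels")
  }
  if (nrow(signals) > 0 && ncol(signals) < 1) {
    stop("segment_len must be positive")
  }
  valid <- if (label_scheme == "five_class") 1:5 else 0:1
  if (length(labels) && !all(labels %in% valid)) {
    stop("labels outside ", paste(range(valid), collapse = ".."),
         " for scheme '", label_scheme, "'")
  }
  if (is.null(class_names)) {
    class_names <- if (label_scheme == "five_class") {
      c("a", "b", "c", "d", "e")
    } else {
      c("non_seizure", "seizure")
    }
  }
  structure(
    list(signals = signals, labels = labels, label_scheme = label_scheme,
         class_names = class_names, sampling_rate = sampling_rate),
    class = "segment_set"
  )
}

#' @export
print.segment_set <- function(x, ...) {
  cat("<segment_set> ", nrow(x$signals), " segments x ", ncol(x$signals),
      " samples (", x$label_scheme, ", ", x$sampling_rate, " Hz)\n", sep = "")
  if (length(x$labels)) {
    tab <- table(factor(x$labels, levels = sort(unique(x$labels))))
    cat("  labels:", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  }
  invisible(x)
}

#' Number of segments in a segment set
#' @param s a `segment_set`.
#' @return integer count of rows.
#' @export
n_segments <- function(s) nrow(s$signals)

#' Segment length (samples per segment)
#' @param s a `segment_set`.
#' @return integer number of columns.
#' @export
segment_length <- function(s) ncol(s$signals)

#' Subset a segment set by row index
#' @param x a `segment_set`.
#' @param i row indices.
#' @param ... ignored.
#' @export
`[.segment_set` <- function(x, i, ...) {
  segment_set(x$signals[i, , drop = FALSE], x$labels[i],
              label_scheme = x$label_scheme, class_names = x$class_names,
              sampling_rate = x$sampling_rate)
}

#' Raw EEG recordings prior to segmentation
#'
#' A `recording_set` holds full-length single-channel recordings (4097
#' samples covering ~23.5 s in the canonical data) before they are cut into
#' fixed-length segments.
#'
#' @param recordings numeric matrix, one row per recording.
#' @param labels integer labels 1..5, one per recording.
#' @param duration_s nominal duration in seconds.
#' @return An object of class `recording_set`.
#' @export
recording_set <- function(recordings, labels, duration_s = 23.5) {
  recordings <- as.matrix(recordings)
  storage.mode(recordings) <- "double"
  labels <- as.integer(labels)
  if (nrow(recordings) != length(labels)) {
    stop("n_recordings mismatch: ", nrow(recordings), " rows but ",
         length(labels), " labels")
  }
  structure(list(recordings = recordings, labels = labels,
                 duration_s = duration_s),
            class = "recording_set")
}

#' @export
print.recording_set <- function(x, ...) {
  cat("<recording_set> ", nrow(x$recordings), " recordings x ",
      ncol(x$recordings), " samples\n", sep = "")
  invisible(x)
}

#' Read a segment CSV in the UCI epileptic-seizure dialect
#'
#' The dialect is one row per 1-second segment: an optional id column (e.g.
#' `"X1.V1.791"`), 178 numeric signal columns, and a final integer label
#' column in 1..5. An optional header row is detected and skipped. When
#' `dialect = "auto"` the id column is detected by a non-numeric first field.
#'
#' @param path file path.
#' @param dialect `"auto"`, `"with_id"` or `"without_id"`.
#' @param segment_len expected number of signal columns (178).
#' @return A five-class [segment_set()], row order preserved.
#' @export
load_uci_csv <- function(path, dialect = c("auto", "with_id", "without_id"),
                         segment_len = 178) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path)

  first <- strsplit(lines[[1]], ",", fixed = TRUE)[[1]]
  # header if the last field of the first line is not an integer label
  has_header <- is.na(suppressWarnings(as.numeric(first[length(first)])))
  if (has_header) lines <- lines[-1]
  if (!length(lines)) stop("no data rows in ", path)

  fields <- strsplit(lines, ",", fixed = TRUE)
  ncols <- lengths(fields)
  if (length(unique(ncols)) != 1) {
    bad <- which(ncols != ncols[[1]])[1]
    stop("malformed row ", bad + has_header, ": ", ncols[bad],
         " fields where ", ncols[1], " expected")
  }
  nc <- ncols[[1]]
  has_id <- switch(dialect,
    with_id = TRUE,
    without_id = FALSE,
    auto = is.na(suppressWarnings(as.numeric(fields[[1]][1])))
  )
  expected <- segment_len + 1L + as.integer(has_id)
  if (nc != expected) {
    stop("wrong column count: expected ", expected, " (",
         if (has_id) "id + " else "", segment_len,
         " signals + label), observed ", nc)
  }
  sig_cols <- (1L + as.integer(has_id)):(nc - 1L)
  parse_row <- function(i) {
    v <- suppressWarnings(as.numeric(fields[[i]][sig_cols]))
    if (anyNA(v)) stop("malformed row ", i + has_header,
                       ": non-numeric signal value")
    v
  }
  signals <- do.call(rbind, lapply(seq_along(fields), parse_row))
  labels <- suppressWarnings(as.integer(
    vapply(fields, function(f) as.numeric(f[nc]), 0)))
  if (anyNA(labels)) {
    stop("malformed row ", which(is.na(labels))[1] + has_header,
         ": non-integer label")
  }
  segment_set(signals, labels, label_scheme = "five_class")
}

#' Write a segment set as a UCI-dialect CSV
#'
#' @param s a [segment_set()].
#' @param path output file path.
#' @param with_id prepend a synthetic id column (`"S<row>"`).
#' @param header write a header line.
#' @return `path`, invisibly.
#' @export
write_uci_csv <- function(s, path, with_id = FALSE, header = TRUE) {
  stopifnot(inherits(s, "segment_set"))
  p <- ncol(s$signals)
  cols <- character(0)
  if (with_id) cols <- "id"
  cols <- c(cols, paste0("X", seq_len(p)), "y")
  body <- apply(s$signals, 1, function(r)
    paste(format(r, trim = TRUE, scientific = FALSE, digits = 10),
          collapse = ","))
  if (with_id) body <- paste(paste0("S", seq_along(body)), body, sep = ",")
  body <- paste(body, s$labels, sep = ",")
  out <- if (header) c(paste(cols, collapse = ","), body) else body
  writeLines(out, path)
  invisible(path)
}

#' Cut raw recordings into fixed-length segments
#'
#' Each recording of length L yields `floor(L / chunk_len)` consecutive
#' non-overlapping chunks; the trailing remainder is discarded (a 4097-sample
#' recording at `chunk_len = 178` yields 23 segments, dropping 3 samples).
#' Each chunk inherits its recording's label.
#'
#' @param rec a [recording_set()].
#' @param chunk_len segment length in samples (178 by convention).
#' @return A five-class [segment_set()].
#' @export
segment_recordings <- function(rec, chunk_len = 178) {
  stopifnot(inherits(rec, "recording_set"))
  if (chunk_len <= 0) stop("chunk_len must be positive")
  L <- ncol(rec$recordings)
  if (chunk_len > L) stop("chunk_len (", chunk_len,
                          ") exceeds recording length (", L, ")")
  k <- L %/% chunk_len
  n <- nrow(rec$recordings)
  signals <- matrix(0, n * k, chunk_len)
  labels <- integer(n * k)
  row <- 1L
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      a <- (j - 1L) * chunk_len + 1L
      signals[row, ] <- rec$recordings[i, a:(a + chunk_len - 1L)]
      labels[row] <- rec$labels[i]
      row <- row + 1L
    }
  }
  segment_set(signals, labels, label_scheme = "five_class")
}

#' Collapse five-class labels to the binary seizure task
#'
#' Class 1 (ictal recordings) becomes the positive "seizure" class (label 1);
#' classes 2-5 become "non-seizure" (label 0). Signals are untouched.
#'
#' @param s a five-class [segment_set()].
#' @return A binary [segment_set()].
#' @export
to_binary <- function(s) {
  stopifnot(inherits(s, "segment_set"))
  if (s$label_scheme != "five_class") {
    stop("to_binary expects a five_class segment_set, got '",
         s$label_scheme, "'")
  }
  segment_set(s$signals, as.integer(s$labels == 1L), label_scheme = "binary",
              sampling_rate = s$sampling_rate)
}

#' Stratified train/test split
#'
#' Samples `test_frac` of each class (rounded) into the test partition so
#' per-class proportions are preserved; the split is disjoint, exhaustive and
#' reproducible under a fixed seed.
#'
#' @param s a [segment_set()].
#' @param test_frac fraction in (0, 1) routed to the test set.
#' @param seed integer RNG seed.
#' @return `list(train = , test = )` of segment sets.
#' @export
stratified_split <- function(s, test_frac = 0.2, seed = 1L) {
  stopifnot(inherits(s, "segment_set"))
  if (test_frac <= 0 || test_frac >= 1) stop("test_frac must be in (0,1)")
  tab <- table(s$labels)
  if (any(tab < 2)) {
    stop("class ", names(tab)[which(tab < 2)[1]],
         " has fewer than 2 members; cannot split")
  }
  test_idx <- integer(0)
  rng <- rng_stream(seed, "stratified_split")
  for (cl in as.integer(names(tab))) {
    idx <- which(s$labels == cl)
    n_test <- max(1L, round(test_frac * length(idx)))
    test_idx <- c(test_idx, rng_sample(rng, idx, n_test))
  }
  test_idx <- sort(test_idx)
  list(train = s[setdiff(seq_len(n_segments(s)), test_idx)],
       test = s[test_idx])
}
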