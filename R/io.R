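#' Construct a spot set
#'
#' A spot set holds the tissue locations the whole pipeline refers to: one
#' row per spot with a unique identifier and 2-D spatial coordinates in the
#' tissue's coordinate units (microns for Visium/MERFISH-style data).
#'
#' @param spot_id character vector of unique spot identifiers.
#' @param x,y numeric coordinates, finite, same length as `spot_id`.
#' @return An object of class `spot_set`: a `data.frame` with columns
#'   `spot_id`, `x`, `y`, preserving input order.
#' @examples
#' spot_set(c("s1", "s2"), x = c(0, 1), y = c(0, 0))
#' @export
spot_set <- function(spot_id, x, y) {
  spot_id <- as.character(spot_id)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(spot_id) < 1L)
    stop("a spot set needs at least one spot")
  if (length(x) != length(spot_id) || length(y) != length(spot_id))
    stop("spot_id, x and y must have equal length")
  dup <- spot_id[duplicated(spot_id)]
  if (length(dup))
    stop("duplicate spot_id: ", paste(unique(dup), collapse = ", "))
  bad <- which(!is.finite(x) | !is.finite(y))
  if (length(bad))
    stop("non-finite coordinate for spot(s): ",
         paste(spot_id[bad], collapse = ", "))
  structure(
    data.frame(spot_id = spot_id, x = x, y = y, stringsAsFactors = FALSE),
    class = c("spot_set", "data.frame")
  )
}

#' Read a spot table from delimited text
#'
#' Expects columns `spot_id`, `x`, `y` (extra columns are ignored). The
#' delimiter is inferred from the file extension (`.tsv`/`.txt` = tab,
#' otherwise comma).
#'
#' @param path path to a CSV/TSV file.
#' @return A [spot_set()].
#' @export
read_spot_table <- function(path) {
  tab <- read_delim_auto(path)
  need <- c("spot_id", "x", "y")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("spot table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  for (cc in c("x", "y")) {
    v <- suppressWarnings(as.numeric(tab[[cc]]))
    bad <- which(is.na(v) & !is.na(tab[[cc]]))
    if (length(bad))
      stop("non-numeric ", cc, " at row ", bad[1L],
           " (spot_id ", tab$spot_id[bad[1L]], ")")
    tab[[cc]] <- v
  }
  spot_set(tab$spot_id, tab$x, tab$y)
}

#' Write a spot table
#' @param spots a [spot_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(spots, path) {
  stopifnot(inherits(spots, "spot_set"))
  utils::write.csv(as.data.frame(spots), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

#' Construct a multi-resolution clustering sequence
#'
#' Bundles a spot set with one partition of it per scale, ordered fine to
#' coarse. Labels are re-encoded per scale to dense integers `1..n_j` in
#' order of first appearance; downstream computation only ever uses the
#' induced spot-ID sets, so the original label codes carry no meaning.
#'
#' @param spots a [spot_set()].
#' @param labels integer matrix, one row per spot (aligned with `spots`),
#'   one column per scale ordered fine to coarse.
#' @param resolutions numeric vector of scale parameters, one per column.
#'   Defaults to a decreasing unit-less index. A warning (not an error) is
#'   emitted if cluster counts are not non-increasing fine to coarse, since
#'   real resolution sweeps can be non-monotone.
#' @return An object of class `clustering_sequence` with elements `spots`,
#'   `labels` (dense-coded integer matrix), `resolutions`, `n_scales`.
#' @export
clustering_sequence <- function(spots, labels, resolutions = NULL) {
  stopifnot(inherits(spots, "spot_set"))
  labels <- as.matrix(labels)
  if (nrow(labels) != nrow(spots))
    stop("labels must have one row per spot (", nrow(spots), " expected, got ",
         nrow(labels), ")")
  if (ncol(labels) < 2L)
    stop("need at least 2 scales")
  if (anyNA(labels))
    stop("labels must be complete: every spot needs a label at every scale")
  if (is.null(resolutions)) {
    resolutions <- as.numeric(colnames(labels))
    if (anyNA(resolutions) || length(resolutions) == 0L)
      resolutions <- rev(seq_len(ncol(labels)))
  }
  if (length(resolutions) != ncol(labels))
    stop("one resolution per scale column required")
  if (any(diff(resolutions) >= 0))
    warning("resolutions are not strictly decreasing; column order is kept")
  dense <- vapply(seq_len(ncol(labels)), function(j) {
    match(labels[, j], unique(labels[, j]))
  }, integer(nrow(labels)))
  counts <- apply(dense, 2L, max)
  if (any(diff(counts) > 0))
    warning("cluster counts increase fine to coarse at some step; ",
            "column order is treated as authoritative")
  dimnames(dense) <- list(spots$spot_id, format(resolutions, trim = TRUE))
  structure(
    list(spots = spots, labels = dense, resolutions = as.numeric(resolutions),
         n_scales = ncol(dense)),
    class = "clustering_sequence"
  )
}

#' @export
print.clustering_sequence <- function(x, ...) {
  counts <- apply(x$labels, 2L, max)
  cat("Multi-resolution clustering sequence\n")
  cat("  spots:  ", nrow(x$spots), "\n", sep = "")
  cat("  scales: ", x$n_scales, " (fine -> coarse)\n", sep = "")
  cat("  resolutions: ", paste(format(x$resolutions, digits = 4),
                               collapse = ", "), "\n", sep = "")
  cat("  clusters/scale: ", paste(counts, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read a label matrix from delimited text
#'
#' Expects a `spot_id` column plus one integer-label column per scale,
#' ordered fine to coarse (column names are read as resolutions when
#' numeric). Every spot of `spots` must appear exactly once.
#'
#' @param path path to a CSV/TSV file.
#' @param spots the [spot_set()] the labels refer to.
#' @return A [clustering_sequence()].
#' @export
read_label_matrix <- function(path, spots) {
  stopifnot(inherits(spots, "spot_set"))
  tab <- read_delim_auto(path)
  if (!"spot_id" %in% names(tab))
    stop("label matrix ", path, " is missing column spot_id")
  tab$spot_id <- as.character(tab$spot_id)
  miss <- setdiff(spots$spot_id, tab$spot_id)
  if (length(miss))
    stop("label matrix is missing spot(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(tab$spot_id, spots$spot_id)
  if (length(extra))
    stop("label matrix has unknown spot(s): ", paste(extra, collapse = ", "))
  tab <- tab[match(spots$spot_id, tab$spot_id), , drop = FALSE]
  lab_cols <- setdiff(names(tab), "spot_id")
  if (length(lab_cols) < 2L)
    stop("label matrix needs at least 2 scale columns")
  lab <- as.matrix(tab[, lab_cols, drop = FALSE])
  num <- suppressWarnings(apply(lab, 2L, as.numeric))
  if (anyNA(num) || any(num != round(num)))
    stop("labels must be integers")
  storage.mode(num) <- "integer"
  colnames(num) <- lab_cols
  clustering_sequence(spots, num)
}

#' Write a label matrix
#' @param seq a [clustering_sequence()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_label_matrix <- function(seq, path) {
  stopifnot(inherits(seq, "clustering_sequence"))
  out <- data.frame(spot_id = seq$spots$spot_id, seq$labels,
                    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a ground-truth annotation
#'
#' Binary (hard) domain annotations used for benchmarking. Unassigned spots
#' are permitted via `NA` or the sentinel label given in `unassigned`.
#'
#' @param spots a [spot_set()].
#' @param labels vector of domain labels, one per spot.
#' @param unassigned optional label value to treat as unassigned (becomes
#'   `NA`).
#' @return An object of class `ground_truth`: list with `spots` and `labels`
#'   (character, `NA` for unassigned).
#' @export
ground_truth <- function(spots, labels, unassigned = NULL) {
  stopifnot(inherits(spots, "spot_set"))
  labels <- as.character(labels)
  if (length(labels) != nrow(spots))
    stop("one label per spot required")
  if (!is.null(unassigned)) labels[labels %in% as.character(unassigned)] <- NA
  if (all(is.na(labels))) stop("annotation has no assigned spot")
  structure(list(spots = spots, labels = labels), class = "ground_truth")
}

#' Read ground-truth annotations from delimited text
#'
#' Expects columns `spot_id` and `domain`; spots of `spots` absent from the
#' table are treated as unassigned.
#'
#' @inheritParams read_label_matrix
#' @param unassigned sentinel label treated as unassigned.
#' @return A [ground_truth()].
#' @export
read_ground_truth <- function(path, spots, unassigned = "") {
  tab <- read_delim_auto(path)
  need <- c("spot_id", "domain")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("truth table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  lab <- as.character(tab$domain)[match(spots$spot_id,
                                        as.character(tab$spot_id))]
  ground_truth(spots, lab, unassigned = unassigned)
}

# spot-index sets of every cluster at one scale, named by dense label
scale_clusters <- function(seq, i) {
  split(seq_len(nrow(seq$labels)), seq$labels[, i])
}
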