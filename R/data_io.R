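#' @title Marker and trait tables
#' @name data_io
#' @description Readers and validators for plain-text genotype and trait
#'   tables. Genotype matrices hold one row per individual and one column per
#'   marker, with integer codes drawn from a declared encoding (allele counts
#'   0/1/2 for codominant markers, presence/absence 0/1 or 0/2 for dominant
#'   markers). Trait tables hold one row per individual and one column per
#'   continuous trait. Missing genotypes are rejected, not imputed.
NULL

.encoding_codes <- list(
  "codominant-012" = c(0, 1, 2),
  "dominant-01"    = c(0, 1),
  "dominant-02"    = c(0, 2)
)

#' Construct a marker matrix
#'
#' @param values numeric matrix, n individuals x p markers, integer genotype
#'   codes.
#' @param sample_ids character vector of n unique individual labels. Defaults
#'   to rownames of `values`.
#' @param marker_ids character vector of p unique marker labels. Defaults to
#'   colnames of `values`.
#' @param encoding one of `"codominant-012"`, `"dominant-01"`, `"dominant-02"`.
#' @return An object of class `marker_matrix`: the numeric matrix with
#'   `sample_ids`/`marker_ids` as dimnames and the encoding as an attribute.
#' @export
marker_matrix <- function(values, sample_ids = rownames(values),
                          marker_ids = colnames(values),
                          encoding = "codominant-012") {
  encoding <- match.arg(encoding, names(.encoding_codes))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(values)))
  if (is.null(marker_ids)) marker_ids <- paste0("marker", seq_len(ncol(values)))
  if (nrow(values) < 2L) stop("a marker matrix needs at least 2 individuals")
  if (ncol(values) < 1L) stop("a marker matrix needs at least 1 marker")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample_ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(marker_ids))
    stop("duplicate marker_ids: ",
         paste(unique(marker_ids[duplicated(marker_ids)]), collapse = ", "))
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing genotype for sample '%s' at marker '%s'",
                 sample_ids[bad[1L]], marker_ids[bad[2L]]))
  }
  codes <- .encoding_codes[[encoding]]
  if (!all(values %in% codes)) {
    bad <- which(!(values %in% codes))[1L]
    idx <- arrayInd(bad, dim(values))
    stop(sprintf(
      "genotype code %s (sample '%s', marker '%s') outside encoding '%s' {%s}",
      format(values[bad]), sample_ids[idx[1L]], marker_ids[idx[2L]],
      encoding, paste(codes, collapse = ",")))
  }
  dimnames(values) <- list(sample_ids, marker_ids)
  structure(values, encoding = encoding, class = c("marker_matrix", "matrix", "array"))
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d individuals x %d markers (%s)\n",
              nrow(x), ncol(x), attr(x, "encoding")))
  invisible(x)
}

#' Construct a trait vector
#'
#' @param values numeric vector of trait values.
#' @param trait_name trait label.
#' @param sample_ids optional individual labels (defaults to names of
#'   `values`).
#' @return An object of class `trait_vector` with attributes `trait_name`,
#'   and `nonnegative` (TRUE when `min(values) >= 0`).
#' @export
trait_vector <- function(values, trait_name = "trait", sample_ids = names(values)) {
  force(sample_ids)
  values <- as.numeric(values)
  if (anyNA(values)) stop("trait vector contains missing values")
  if (!is.null(sample_ids)) {
    if (anyDuplicated(sample_ids)) stop("duplicate sample_ids in trait vector")
    names(values) <- sample_ids
  }
  structure(values, trait_name = trait_name,
            nonnegative = min(values) >= 0, class = "trait_vector")
}

#' @export
print.trait_vector <- function(x, ...) {
  cat(sprintf("trait_vector '%s': n=%d, range [%g, %g]%s\n",
              attr(x, "trait_name"), length(x), min(x), max(x),
              if (attr(x, "nonnegative")) ", nonnegative" else ""))
  invisible(x)
}

# detect comma vs tab from the header line
.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header)))
  n_com <- lengths(regmatches(header, gregexpr(",", header)))
  if (n_tab >= n_com && n_tab > 0L) "\t" else ","
}

#' Read a genotype table
#'
#' Reads a delimited text file (comma or tab, auto-detected) whose header row
#' lists marker identifiers and whose first column lists sample identifiers.
#' Every cell must be a genotype code of the declared encoding; missing or
#' out-of-set cells are an error (imputation is deliberately not performed).
#'
#' @param path file path.
#' @param encoding genotype encoding, see [marker_matrix()].
#' @return A [marker_matrix()].
#' @export
read_marker_matrix <- function(path, encoding = "codominant-012") {
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          comment.char = "", quote = "\"")
  if (ncol(df) < 2L) stop("marker file needs a sample-id column plus markers")
  sample_ids <- df[[1L]]
  body <- df[-1L]
  mm <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(df))))
  mm <- matrix(mm, nrow = nrow(df),
               dimnames = list(sample_ids, colnames(body)))
  blank <- !is.na(as.matrix(body)) & trimws(as.matrix(body)) == ""
  mm[blank] <- NA_real_
  marker_matrix(mm, sample_ids, colnames(body), encoding)
}

#' Write a genotype table
#'
#' Inverse of [read_marker_matrix()]; round-trips values and identifiers
#' exactly (integer codes).
#'
#' @param x a [marker_matrix()].
#' @param path output path.
#' @param sep field separator, `","` or `"\t"`.
#' @export
write_marker_matrix <- function(x, path, sep = ",") {
  df <- data.frame(id = rownames(x), as.data.frame(unclass(x)[, , drop = FALSE]),
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trait table
#'
#' Reads a delimited text file with sample identifiers in the first column and
#' one numeric trait per remaining column.
#'
#' @param path file path.
#' @return A named list of [trait_vector()]s, one per trait column.
#' @export
read_traits <- function(path) {
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          comment.char = "", quote = "\"")
  if (ncol(df) < 2L) stop("trait file needs a sample-id column plus traits")
  sample_ids <- df[[1L]]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample_ids in trait file: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  out <- lapply(names(df)[-1L], function(tr) {
    raw <- df[[tr]]
    vals <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(vals))
    if (length(bad))
      stop(sprintf("non-numeric trait value '%s' for sample '%s' in trait '%s'",
                   raw[bad[1L]], sample_ids[bad[1L]], tr))
    trait_vector(vals, trait_name = tr, sample_ids = sample_ids)
  })
  names(out) <- names(df)[-1L]
  out
}

#' Shift a trait to be nonnegative
#'
#' Subtracts the minimum so the smallest value becomes exactly zero. NDCG
#' assumes nonnegative gains; shifting changes no pairwise ordering. Shifting
#' is applied to the whole dataset before any train/test split: the leaked
#' quantity is a single constant offset, to which every implemented measure
#' except raw (unnormalized) DCG is invariant.
#'
#' @param y a [trait_vector()] or numeric vector.
#' @return A trait vector with `min == 0` and `nonnegative = TRUE`.
#' @export
shift_nonnegative <- function(y) {
  vals <- as.numeric(y) - min(as.numeric(y))
  trait_vector(vals,
               trait_name = attr(y, "trait_name") %||% "trait",
               sample_ids = names(y))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Align a marker matrix with trait vectors
#'
#' Restricts both inputs to their common samples, ordered as in the marker
#' table, and returns them bundled as a dataset. Samples present in only one
#' input are dropped with a warning.
#'
#' @param markers a [marker_matrix()].
#' @param traits a single [trait_vector()] or list of them; all must carry
#'   sample names.
#' @return A `gs_dataset`: list with elements `markers` and `traits` sharing
#'   sample order.
#' @export
align <- function(markers, traits) {
  if (inherits(traits, "trait_vector")) traits <- list(traits)
  for (tr in traits)
    if (is.null(names(tr))) stop("trait vectors must carry sample names to align")
  common <- rownames(markers)
  for (tr in traits) common <- intersect(common, names(tr))
  if (length(common) == 0L) stop("no samples in common between markers and traits")
  if (length(common) < 2L) stop("fewer than 2 samples in common after alignment")
  keep <- rownames(markers)[rownames(markers) %in% common]
  dropped <- setdiff(union(rownames(markers), unlist(lapply(traits, names))), keep)
  if (length(dropped))
    warning("dropping samples absent from one input: ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "")
  mk <- marker_matrix(unclass(markers)[keep, , drop = FALSE],
                      sample_ids = keep, marker_ids = colnames(markers),
                      encoding = attr(markers, "encoding"))
  tr_out <- lapply(traits, function(tr)
    trait_vector(as.numeric(tr)[match(keep, names(tr))],
                 trait_name = attr(tr, "trait_name") %||% "trait",
                 sample_ids = keep))
  names(tr_out) <- vapply(tr_out, attr, "", "trait_name")
  structure(list(markers = mk, traits = tr_out), class = "gs_dataset")
}

#' @export
print.gs_dataset <- function(x, ...) {
  cat(sprintf("gs_dataset: %d individuals, %d markers, %d trait(s): %s\n",
              nrow(x$markers), ncol(x$markers), length(x$traits),
              paste(names(x$traits), collapse = ", ")))
  invisible(x)
}
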