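#' Taxon-by-sample read matrix
#'
#' Container for a metabarcoding count (or relative-abundance) table for
#' one marker: a numeric taxa x samples matrix with unique row and column
#' names.
#'
#' @param counts Numeric matrix, taxa as rows, samples as columns, with
#'   dimnames. Counts mode requires non-negative integers; relative mode
#'   requires every non-empty column to sum to 1 (tolerance 1e-9).
#' @param marker Marker label (e.g. "18S", "COI").
#' @param mode `"counts"` or `"relative"`.
#' @return An object of class `read_matrix` with elements `marker`,
#'   `counts`, `mode`.
#' @export
read_matrix <- function(counts, marker, mode = c("counts", "relative")) {
  mode <- match.arg(mode)
  counts <- as.matrix(counts)
  if ((is.null(rownames(counts)) && nrow(counts) > 0) ||
      (is.null(colnames(counts)) && ncol(counts) > 0)) {
    stop("read matrix needs taxon and sample names")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate taxon ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (!is.numeric(counts) || anyNA(counts)) stop("non-numeric cells")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at taxon '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  if (mode == "counts" && any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at taxon '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  if (mode == "relative") {
    cs <- colSums(counts)
    if (any(cs > 0 & abs(cs - 1) > 1e-9)) {
      stop("relative-mode columns must sum to 1")
    }
  }
  structure(list(marker = marker, counts = counts, mode = mode),
            class = "read_matrix")
}

#' @export
print.read_matrix <- function(x, ...) {
  cat(sprintf("read_matrix [%s, %s]: %d taxa x %d samples\n",
              x$marker, x$mode, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' @export
dim.read_matrix <- function(x) dim(x$counts)

#' Read / write a read matrix as TSV
#'
#' TSV layout: header row of sample ids, first column `taxon_id`, integer
#' cells. Write then read is the identity.
#'
#' @param path File path.
#' @param marker Marker label to attach.
#' @param mode Matrix mode, `"counts"` (default) or `"relative"`.
#' @return A [read_matrix()].
#' @export
read_read_matrix <- function(path, marker, mode = "counts") {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "taxon_id") stop("first column must be 'taxon_id'")
  if (anyDuplicated(df$taxon_id)) {
    stop("duplicate taxon id: ", df$taxon_id[duplicated(df$taxon_id)][1])
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$taxon_id
  if (!is.numeric(m)) {
    num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m)))
    bad <- which(is.na(num) & !is.na(m), arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("non-numeric cell at taxon '%s', sample '%s'",
                   rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
    }
    dimnames(num) <- dimnames(m)
    m <- num
  }
  read_matrix(m, marker = marker, mode = mode)
}

#' @rdname read_read_matrix
#' @param matrix A [read_matrix()].
#' @export
write_read_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "read_matrix"))
  df <- data.frame(taxon_id = rownames(matrix$counts), matrix$counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge technical replicates by summing reads
#'
#' Collapses technical-replicate columns into one column per biological
#' sample by summing reads cell-wise. Total reads are conserved.
#'
#' @param matrix A counts-mode [read_matrix()] whose columns are technical
#'   replicates, or a list of such matrices sharing marker and taxa
#'   (combined column-wise first).
#' @param replicate_map Named character vector mapping replicate sample id
#'   to biological sample id. Every column must be mapped exactly once.
#' @return A counts-mode [read_matrix()] with one column per biological id.
#' @export
merge_replicates <- function(matrix, replicate_map) {
  if (is.list(matrix) && !inherits(matrix, "read_matrix")) {
    mk <- unique(vapply(matrix, function(m) m$marker, character(1)))
    if (length(mk) != 1) stop("replicate matrices must share a marker")
    taxa <- lapply(matrix, function(m) rownames(m$counts))
    if (!all(vapply(taxa, identical, logical(1), taxa[[1]]))) {
      stop("replicate matrices must share taxa")
    }
    matrix <- read_matrix(do.call(cbind, lapply(matrix, `[[`, "counts")),
                          marker = mk, mode = "counts")
  }
  stopifnot(inherits(matrix, "read_matrix"), matrix$mode == "counts")
  reps <- colnames(matrix$counts)
  if (anyDuplicated(names(replicate_map))) {
    dup <- names(replicate_map)[duplicated(names(replicate_map))][1]
    stop("replicate '", dup, "' mapped to more than one biological sample")
  }
  unmapped <- setdiff(reps, names(replicate_map))
  if (length(unmapped)) {
    stop("unmapped replicate(s): ", paste(unmapped, collapse = ", "))
  }
  bio <- replicate_map[reps]
  out <- vapply(unique(bio), function(b) {
    rowSums(matrix$counts[, bio == b, drop = FALSE])
  }, numeric(nrow(matrix$counts)))
  read_matrix(out, marker = matrix$marker, mode = "counts")
}

#' Convert counts to relative abundance
#'
#' Divides each column by its read total. All-zero columns stay all-zero
#' and are flagged in the `empty_samples` attribute. No rarefaction is
#' applied.
#'
#' @param matrix A counts-mode [read_matrix()].
#' @return A relative-mode [read_matrix()] with attribute `empty_samples`.
#' @export
to_relative <- function(matrix) {
  stopifnot(inherits(matrix, "read_matrix"))
  if (matrix$mode != "counts") stop("matrix is already relative")
  cs <- colSums(matrix$counts)
  rel <- sweep(matrix$counts, 2, ifelse(cs == 0, 1, cs), "/")
  out <- read_matrix(rel, marker = matrix$marker, mode = "relative")
  attr(out, "empty_samples") <- colnames(matrix$counts)[cs == 0]
  out
}

#' Combine markers as independent observations
#'
#' Row-binds matrices from different markers over an identical sample set,
#' prefixing taxon ids with the marker label. No cross-marker
#' deduplication: the same taxonomy observed at two markers stays two rows
#' (each OTU/ASV is an independent observation of a species).
#'
#' @param matrices List of [read_matrix()] objects with identical sample
#'   sets and modes.
#' @return A [read_matrix()] with marker `"combined"`.
#' @export
combine_markers <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  if (length(matrices) == 1) return(matrices[[1]])
  samples <- lapply(matrices, function(m) colnames(m$counts))
  for (i in seq_along(matrices)[-1]) {
    extra <- setdiff(samples[[i]], samples[[1]])
    miss <- setdiff(samples[[1]], samples[[i]])
    if (length(extra) || length(miss)) {
      stop("sample sets differ: only in marker ", matrices[[i]]$marker, ": [",
           paste(extra, collapse = ", "), "]; missing: [",
           paste(miss, collapse = ", "), "]")
    }
  }
  modes <- unique(vapply(matrices, `[[`, character(1), "mode"))
  if (length(modes) != 1) stop("matrices must share a mode")
  blocks <- lapply(matrices, function(m) {
    b <- m$counts[, samples[[1]], drop = FALSE]
    rownames(b) <- paste(m$marker, rownames(b), sep = ":")
    b
  })
  out <- do.call(rbind, blocks)
  # combined relative columns sum to the number of markers; renormalise
  if (modes == "relative") {
    cs <- colSums(out)
    out <- sweep(out, 2, ifelse(cs == 0, 1, cs), "/")
  }
  read_matrix(out, marker = "combined", mode = modes)
}
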