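#' Symmetrise a connectivity matrix
#'
#' Tractography yields directed counts; symmetry is enforced by averaging
#' the two directions.  The diagonal is zeroed: self-coupling is part of
#' the node model, not the network.
#'
#' @param M Square non-negative numeric matrix.
#' @return The symmetrised matrix with zero diagonal.
#' @export
symmetrize <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("matrix must be square")
  if (any(M < 0)) stop("matrix entries must be non-negative")
  S <- (M + t(M)) / 2
  diag(S) <- 0
  S
}

#' Normalise a matrix by its maximum entry
#'
#' @param M Non-negative numeric matrix.
#' @return `M / max(M)`; an all-zero matrix is returned unchanged with a
#'   warning.
#' @export
max_normalize <- function(M) {
  M <- as.matrix(M)
  mx <- max(M)
  if (mx == 0) {
    warning("all-zero matrix cannot be max-normalised; returned unchanged")
    return(M)
  }
  M / mx
}

#' Convert fibre lengths to conduction delays
#'
#' @param L_mm Matrix (or vector) of fibre lengths in millimetres.
#' @param v_gl_m_per_s Signal speed in metres per second.
#' @return Delays in milliseconds (same shape as `L_mm`): `L / v`, since
#'   mm / (m/s) = ms.
#' @export
delays_from_lengths <- function(L_mm, v_gl_m_per_s) {
  stopifnot(v_gl_m_per_s > 0)
  if (any(L_mm < 0)) stop("fibre lengths must be non-negative")
  L_mm / v_gl_m_per_s
}

#' Construct a validated connectome
#'
#' @param C Coupling-strength matrix: symmetric, non-negative, zero
#'   diagonal, maximum entry 1 (unless all-zero).
#' @param D Delay matrix in ms: symmetric, non-negative. May be `NULL` for
#'   delay-free toy networks (treated as all-zero).
#' @param labels Optional character vector of region names.
#' @return An object of class `aln_connectome`.
#' @export
connectome <- function(C, D = NULL, labels = NULL) {
  C <- as.matrix(C)
  n <- nrow(C)
  if (ncol(C) != n) stop("coupling matrix must be square")
  if (is.null(D)) D <- matrix(0, n, n)
  D <- as.matrix(D)
  if (!all(dim(D) == c(n, n))) stop("delay matrix shape must match C")
  if (any(C < 0) || any(D < 0)) stop("C and D must be non-negative")
  if (max(abs(C - t(C))) > 1e-12 || max(abs(D - t(D))) > 1e-9) {
    stop("C and D must be symmetric (use symmetrize() first)")
  }
  if (any(diag(C) != 0)) stop("C must have a zero diagonal")
  if (max(C) > 0 && abs(max(C) - 1) > 1e-12) {
    stop("C must be max-normalised (use max_normalize() first)")
  }
  if (is.null(labels)) labels <- sprintf("region_%02d", seq_len(n))
  if (length(labels) != n) stop("need one label per region")
  dimnames(C) <- dimnames(D) <- NULL
  structure(list(n = n, C = C, D = D, labels = as.character(labels)),
            class = "aln_connectome")
}

#' Post-process a raw fibre-count matrix into a coupling matrix
#'
#' Applies the standard pipeline: symmetrise (average the two directions,
#' zero the diagonal) then divide by the maximum entry.
#'
#' @param M Raw square non-negative matrix.
#' @return Processed matrix satisfying all connectome invariants.
#' @export
process_fiber_counts <- function(M) {
  max_normalize(symmetrize(M))
}

#' Average connectomes across subjects
#'
#' Individual matrices are processed (symmetrised, max-normalised) first,
#' then averaged arithmetically and re-normalised, so that every subject
#' contributes on the same scale.
#'
#' @param mats List of square non-negative matrices of equal size.
#' @return The average coupling matrix (max-normalised).
#' @export
average_connectomes <- function(mats) {
  stopifnot(is.list(mats), length(mats) >= 1)
  proc <- lapply(mats, process_fiber_counts)
  avg <- Reduce(`+`, proc) / length(proc)
  max_normalize(avg)
}

#' Read / write connectome matrices as delimited text
#'
#' `write_connectome()` stores the coupling matrix, fibre-length (or delay)
#' matrix and labels as three tab-separated files in `dir`;
#' `load_connectome()` reads them back, validates shapes and label
#' consistency and derives delays from lengths.
#'
#' @param conn An `aln_connectome` object.
#' @param dir Directory for the three files (`coupling.tsv`,
#'   `lengths_mm.tsv`, `labels.txt`).
#' @param lengths_mm Fibre-length matrix (mm) written alongside `conn$C`;
#'   if `NULL`, delays are converted back to lengths with `v_gl_m_per_s`.
#' @param v_gl_m_per_s Signal speed used for the length/delay conversion.
#' @return `write_connectome()` returns `dir` invisibly;
#'   `load_connectome()` returns an `aln_connectome`.
#' @export
write_connectome <- function(conn, dir, lengths_mm = NULL,
                             v_gl_m_per_s = 20) {
  stopifnot(inherits(conn, "aln_connectome"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(lengths_mm)) lengths_mm <- conn$D * v_gl_m_per_s
  write.table(conn$C, file.path(dir, "coupling.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE)
  write.table(lengths_mm, file.path(dir, "lengths_mm.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE)
  writeLines(conn$labels, file.path(dir, "labels.txt"))
  invisible(dir)
}

#' @rdname write_connectome
#' @export
load_connectome <- function(dir, v_gl_m_per_s = 20) {
  fC <- file.path(dir, "coupling.tsv")
  fL <- file.path(dir, "lengths_mm.tsv")
  fl <- file.path(dir, "labels.txt")
  for (f in c(fC, fL, fl)) {
    if (!file.exists(f)) stop("missing connectome file: ", f)
  }
  C <- as.matrix(read.table(fC, sep = "\t"))
  L <- as.matrix(read.table(fL, sep = "\t"))
  labels <- readLines(fl)
  dimnames(C) <- dimnames(L) <- NULL
  if (nrow(C) != length(labels)) {
    stop(sprintf("label file lists %d regions but matrix has %d rows",
                 length(labels), nrow(C)))
  }
  connectome(C, delays_from_lengths(L, v_gl_m_per_s), labels)
}

#' @export
print.aln_connectome <- function(x, ...) {
  dens <- mean(x$C[upper.tri(x$C)] > 0)
  cat(sprintf(
    "Connectome: %d regions, density %.2f, mean row strength %.2f, max delay %.1f ms\n",
    x$n, dens, mean(rowSums(x$C)), max(x$D)))
  invisible(x)
}
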