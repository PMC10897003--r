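#' Region-to-functional-network partition
#'
#' Maps every region to one of the seven canonical resting-state networks
#' and derives the two super-groups: association = {Def, Cont, Sal/VAttn},
#' sensory = {SomMot, Vis, DAttn}.  The limbic network belongs to neither.
#'
#' @param network Character vector (one entry per region) with values in
#'   `c("SomMot", "Cont", "Def", "Sal/VAttn", "DAttn", "Lim", "Vis")`.
#' @param labels Optional region names.
#' @return An object of class `aln_partition`.
#' @export
partition <- function(network, labels = NULL) {
  valid <- c("SomMot", "Cont", "Def", "Sal/VAttn", "DAttn", "Lim", "Vis")
  network <- as.character(network)
  if (!all(network %in% valid)) {
    stop("unknown network label(s): ",
         paste(setdiff(unique(network), valid), collapse = ", "))
  }
  if (is.null(labels)) labels <- sprintf("region_%02d", seq_along(network))
  stopifnot(length(labels) == length(network))
  structure(list(network = network, labels = as.character(labels),
                 association = c("Def", "Cont", "Sal/VAttn"),
                 sensory = c("SomMot", "Vis", "DAttn")),
            class = "aln_partition")
}

#' Read / write a partition as a two-column table
#' @param part An `aln_partition` object.
#' @param path File path (tab-separated: region, network).
#' @return `write_partition()` returns `path` invisibly; `read_partition()`
#'   an `aln_partition`.
#' @export
write_partition <- function(part, path) {
  stopifnot(inherits(part, "aln_partition"))
  write.table(data.frame(region = part$labels, network = part$network),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE,
                  colClasses = "character")
  partition(d$network, d$region)
}

bold_matrix <- function(bold) {
  if (inherits(bold, "bold_series")) bold$bold else as.matrix(bold)
}

#' Functional connectivity matrix
#'
#' Pairwise Pearson correlations of the regional BOLD time courses over
#' the whole acquisition.
#'
#' @param bold A `bold_series` or a regions x time matrix.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
functional_connectivity <- function(bold) {
  m <- bold_matrix(bold)
  if (ncol(m) < 3) stop("need at least 3 time points")
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    stop("constant BOLD series in region(s): ",
         paste(which(sds == 0), collapse = ", "))
  }
  FC <- cor(t(m))
  dimnames(FC) <- NULL
  FC
}

#' Global brain connectivity
#'
#' Region-wise GBC is the mean functional connectivity of a region to the
#' other regions; the global value is the mean over regions.  By default
#' the self-correlation is excluded and the sum divided by (n - 1); set
#' `include_self = TRUE` for the literal mean over all n entries of a row
#' (an affine shift of the default that leaves group differences intact).
#'
#' @param FC Functional connectivity matrix.
#' @param include_self Include the unit diagonal in the average?
#' @return List with `gbc_region` (vector) and `gbc_global` (scalar).
#' @export
gbc <- function(FC, include_self = FALSE) {
  FC <- as.matrix(FC)
  n <- nrow(FC)
  stopifnot(ncol(FC) == n, n >= 2)
  g <- if (include_self) rowSums(FC) / n else (rowSums(FC) - diag(FC)) / (n - 1)
  list(gbc_region = as.numeric(g), gbc_global = mean(g))
}

#' Sub-network and super-group GBC averages
#'
#' @param gbc_region Region-wise GBC values.
#' @param part An [partition()] object covering the same regions.
#' @return A tibble with one row per group (seven networks plus
#'   `association` and `sensory`) and columns `group`, `n_regions`,
#'   `gbc`.
#' @export
subnetwork_gbc <- function(gbc_region, part) {
  stopifnot(inherits(part, "aln_partition"),
            length(gbc_region) == length(part$network))
  groups <- c(sort(unique(part$network)),
              "association", "sensory")
  members <- function(g) {
    if (g == "association") part$network %in% part$association
    else if (g == "sensory") part$network %in% part$sensory
    else part$network == g
  }
  tibble::tibble(
    group = groups,
    n_regions = vapply(groups, function(g) sum(members(g)), integer(1),
                       USE.NAMES = FALSE),
    gbc = vapply(groups, function(g) mean(gbc_region[members(g)]),
                 numeric(1), USE.NAMES = FALSE))
}

# reflective (odd) padding about the end points
reflect_pad <- function(x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1)
  c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
}

#' Narrowband zero-phase band-pass filter
#'
#' Second-order Butterworth band-pass applied forward and backward
#' (zero phase) with reflective padding at both ends; the default band is
#' the 0.04-0.07 Hz range used for the phase-synchrony measures.
#'
#' @param bold A `bold_series` or regions x time matrix.
#' @param TR_s Repetition time in seconds (taken from the object if
#'   omitted).
#' @param low,high Band edges in Hz; `high` must stay below Nyquist.
#' @return Filtered object of the same type.
#' @export
bandpass <- function(bold, TR_s = NULL, low = 0.04, high = 0.07) {
  is_series <- inherits(bold, "bold_series")
  if (is_series && is.null(TR_s)) TR_s <- bold$TR
  if (is.null(TR_s)) stop("TR_s must be supplied for a bare matrix")
  m <- bold_matrix(bold)
  nyq <- 0.5 / TR_s
  if (high >= nyq) stop("upper band edge must be below the Nyquist frequency")
  stopifnot(low > 0, low < high)
  bf <- signal::butter(2, c(low, high) / nyq, type = "pass")
  ord <- max(length(bf$b), length(bf$a)) - 1
  if (ncol(m) <= 3 * ord) {
    stop(sprintf("series length %d too short for the filter (need > %d)",
                 ncol(m), 3 * ord))
  }
  pad <- min(ncol(m) - 1, 3 * ord)
  filt1 <- function(x) {
    xe <- reflect_pad(x, pad)
    y <- as.numeric(signal::filter(bf, xe))
    y <- rev(as.numeric(signal::filter(bf, rev(y))))
    y[(pad + 1):(pad + length(x))]
  }
  fm <- t(apply(m, 1, filt1))
  if (is_series) {
    bold$bold <- fm
    bold
  } else {
    fm
  }
}

#' Analytic signal via the frequency domain
#'
#' @param x Real numeric vector.
#' @return Complex vector whose real part is `x` and whose argument is the
#'   instantaneous phase.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Kuramoto order parameter, synchrony and metastability
#'
#' Instantaneous phases come from the analytic signal of each (already
#' band-passed) regional series; `R(t)` is the modulus of the mean unit
#' phasor across regions, synchrony its time average and metastability its
#' standard deviation over time.
#'
#' @param filtered_bold Band-passed `bold_series` or regions x time matrix.
#' @param min_cycles Warn when the series is shorter than this many cycles
#'   of the band centre (phase estimates become window-dominated).
#' @param band Band (Hz) used only for the cycle-count warning.
#' @return List with `R_t` (vector over time), `mean_R`, `metastability`
#'   and the phase matrix `phi`.
#' @export
kuramoto <- function(filtered_bold, min_cycles = 5, band = c(0.04, 0.07)) {
  m <- bold_matrix(filtered_bold)
  TR <- if (inherits(filtered_bold, "bold_series")) filtered_bold$TR else NULL
  phi <- t(apply(m, 1, function(x) Arg(analytic_signal(x))))
  z <- exp(1i * phi)
  R_t <- Mod(colMeans(z))
  if (!is.null(TR)) {
    cycles <- ncol(m) * TR * mean(band)
    if (cycles < min_cycles) {
      warning(sprintf(
        "series spans %.1f cycles of the %.3g-%.3g Hz band (< %g); synchrony/metastability are window-dominated",
        cycles, band[1], band[2], min_cycles))
    }
  }
  list(R_t = R_t, mean_R = mean(R_t), metastability = sd(R_t), phi = phi)
}

#' All connectivity and dynamics measures for one subject
#'
#' Computes the functional connectivity matrix, region-wise/global/
#' sub-network GBC, and the band-passed phase-synchrony measures for one
#' regions x time BOLD table (simulated or empirical).
#'
#' @param bold A `bold_series` (or matrix plus `TR_s`).
#' @param part Optional [partition()] for sub-network averages.
#' @param TR_s TR override for bare matrices.
#' @param gbc_include_self Diagonal convention passed to [gbc()].
#' @param band Narrow band (Hz) for the synchrony measures.
#' @return An object of class `metrics_report`.
#' @export
compute_metrics <- function(bold, part = NULL, TR_s = NULL,
                            gbc_include_self = FALSE,
                            band = c(0.04, 0.07)) {
  if (!inherits(bold, "bold_series")) {
    if (is.null(TR_s)) stop("TR_s must be supplied for a bare matrix")
    bold <- structure(list(bold = as.matrix(bold), TR = TR_s),
                      class = "bold_series")
  }
  FC <- functional_connectivity(bold)
  g <- gbc(FC, include_self = gbc_include_self)
  sub <- if (!is.null(part)) subnetwork_gbc(g$gbc_region, part) else NULL
  fb <- bandpass(bold, low = band[1], high = band[2])
  ku <- suppressWarnings(kuramoto(fb, band = band))
  rep <- list(FC = FC, gbc_region = g$gbc_region,
              gbc_global = g$gbc_global, subnetworks = sub,
              gbc_association = if (!is.null(sub))
                sub$gbc[sub$group == "association"] else NA_real_,
              gbc_sensory = if (!is.null(sub))
                sub$gbc[sub$group == "sensory"] else NA_real_,
              mean_R = ku$mean_R, metastability = ku$metastability,
              R_t = ku$R_t, TR = bold$TR)
  class(rep) <- "metrics_report"
  rep
}

#' Flatten a metrics report to one row for group statistics
#'
#' @param report A `metrics_report`.
#' @return A one-row tibble with the scalar measures (global GBC,
#'   association/sensory GBC, per-network GBC where available, synchrony,
#'   metastability).
#' @export
metrics_row <- function(report) {
  stopifnot(inherits(report, "metrics_report"))
  row <- tibble::tibble(gbc_global = report$gbc_global,
                        gbc_association = report$gbc_association,
                        gbc_sensory = report$gbc_sensory,
                        mean_R = report$mean_R,
                        metastability = report$metastability)
  if (!is.null(report$subnetworks)) {
    nets <- report$subnetworks
    nets <- nets[!nets$group %in% c("association", "sensory"), ]
    for (k in seq_len(nrow(nets))) {
      row[[paste0("gbc_", gsub("[^A-Za-z]", "", nets$group[k]))]] <-
        nets$gbc[k]
    }
  }
  row
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "Metrics: %d regions, %d volumes (TR %g s); GBC %.3f, mean R %.3f, metastability %.3f\n",
    nrow(x$FC), length(x$R_t), x$TR, x$gbc_global, x$mean_R,
    x$metastability))
  invisible(x)
}
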