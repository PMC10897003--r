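#' Balloon-Windkessel hemodynamic parameters
#'
#' Defaults follow the standard convention for this model family:
#' signal decay kappa = 0.65 1/s, flow elimination gamma = 0.41 1/s,
#' transit time tau_h = 0.98 s, Grubb exponent 0.32, resting oxygen
#' extraction 0.34, resting venous volume 0.02, and output coefficients
#' k1 = 7*rho_E, k2 = 2, k3 = 2*rho_E - 0.2.
#'
#' @param kappa Vasodilatory signal decay rate (1/s).
#' @param gamma Flow-dependent elimination rate (1/s).
#' @param tau_h Hemodynamic transit time (s).
#' @param a_g Grubb exponent (dimensionless).
#' @param rho_E Resting oxygen extraction fraction.
#' @param V0 Resting venous volume fraction.
#' @param k1,k2,k3 BOLD output coefficients.
#' @param drive_scale Multiplier applied to the mean-centred excitatory
#'   rate (kHz) before it enters the vasodilatory signal equation.
#' @return An object of class `hemo_params`.
#' @export
hemo_params <- function(kappa = 0.65, gamma = 0.41, tau_h = 0.98,
                        a_g = 0.32, rho_E = 0.34, V0 = 0.02,
                        k1 = 7 * rho_E, k2 = 2, k3 = 2 * rho_E - 0.2,
                        drive_scale = 1) {
  stopifnot(kappa > 0, gamma > 0, tau_h > 0, a_g > 0, rho_E > 0, rho_E < 1,
            V0 > 0, drive_scale > 0)
  p <- list(kappa = kappa, gamma = gamma, tau_h = tau_h, a_g = a_g,
            rho_E = rho_E, V0 = V0, k1 = k1, k2 = k2, k3 = k3,
            drive_scale = drive_scale)
  class(p) <- "hemo_params"
  p
}

#' Convert excitatory population rates to BOLD
#'
#' Integrates, per region, the four-state Balloon-Windkessel system
#' (vasodilatory signal s, inflow f, venous volume v, deoxyhemoglobin q)
#' driven by the mean-centred, scaled excitatory rate, and emits the
#' percent-signal-change BOLD output
#' `100 * V0 * (k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v))` decimated to the
#' repetition time `TR_s`.
#'
#' @param rate_E Matrix (regions x time) of non-negative rates in kHz.
#' @param dt_ms Sampling step of `rate_E` in ms.
#' @param params A [hemo_params()] object.
#' @param TR_s Output repetition time (s).
#' @param dt_int_ms Integration step in ms (rate input is repeated to this
#'   resolution if finer than `dt_ms`).
#' @return An object of class `bold_series`: matrix `bold`
#'   (regions x volumes, percent signal change) and `TR` (s).
#' @export
bold_from_rates <- function(rate_E, dt_ms = 1, params = hemo_params(),
                            TR_s = 2, dt_int_ms = dt_ms) {
  if (inherits(rate_E, "aln_sim")) {
    dt_ms <- rate_E$provenance$output_dt
    if (missing(dt_int_ms)) dt_int_ms <- dt_ms
    rate_E <- rate_E$rate_E
  }
  rate_E <- as.matrix(rate_E)
  if (any(!is.finite(rate_E))) stop("rate input contains non-finite values")
  if (any(rate_E < 0)) stop("rate input must be non-negative")
  stopifnot(inherits(params, "hemo_params"), TR_s > 0, dt_ms > 0,
            dt_int_ms > 0, dt_int_ms <= dt_ms)

  n <- nrow(rate_E)
  rep_fac <- as.integer(round(dt_ms / dt_int_ms))
  stopifnot(abs(rep_fac * dt_int_ms - dt_ms) < 1e-9)
  x_base <- (rate_E - rowMeans(rate_E)) * params$drive_scale
  Tn <- ncol(rate_E) * rep_fac
  dt_s <- dt_int_ms / 1000
  keep_every <- as.integer(round(TR_s * 1000 / dt_int_ms))
  stopifnot(keep_every >= 1)
  n_vol <- Tn %/% keep_every
  out <- matrix(NA_real_, n, n_vol)

  s <- numeric(n); f <- rep(1, n); v <- rep(1, n); q <- rep(1, n)
  inv_ag <- 1 / params$a_g
  ki <- 0L
  for (t in seq_len(Tn)) {
    x <- x_base[, ((t - 1L) %/% rep_fac) + 1L]
    fp <- pmax(f, 1e-6)
    E <- 1 - (1 - params$rho_E)^(1 / fp)
    ds <- x - params$kappa * s - params$gamma * (f - 1)
    df <- s
    dv <- (f - v^inv_ag) / params$tau_h
    dq <- (fp * E / params$rho_E - q * v^(inv_ag - 1)) / params$tau_h
    s <- s + dt_s * ds
    f <- f + dt_s * df
    v <- pmax(v + dt_s * dv, 1e-6)
    q <- pmax(q + dt_s * dq, 1e-6)
    if (t %% keep_every == 0L) {
      ki <- ki + 1L
      out[, ki] <- 100 * params$V0 *
        (params$k1 * (1 - q) + params$k2 * (1 - q / v) +
           params$k3 * (1 - v))
    }
  }
  structure(list(bold = out, TR = TR_s, params = unclass(params)),
            class = "bold_series")
}

#' Write / read a BOLD table as delimited text
#'
#' Regions x volumes, tab-separated, with the TR recorded in a `# TR_s:`
#' header line.  The same format serves simulated and empirical data.
#'
#' @param bold A `bold_series` object (or bare matrix plus `TR`).
#' @param path Output file.
#' @param TR TR in seconds when `bold` is a bare matrix.
#' @return `write_bold()` returns `path` invisibly; `read_bold()` a
#'   `bold_series`.
#' @export
write_bold <- function(bold, path, TR = NULL) {
  if (inherits(bold, "bold_series")) {
    m <- bold$bold
    TR <- bold$TR
  } else {
    m <- as.matrix(bold)
    if (is.null(TR)) stop("TR must be given when writing a bare matrix")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# TR_s: %.17g", TR), con)
  write.table(m, con, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bold
#' @export
read_bold <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!grepl("^# TR_s:", hdr)) {
    stop("'", path, "' has no '# TR_s:' header line")
  }
  TR <- as.numeric(sub("^# TR_s:", "", hdr))
  m <- as.matrix(read.table(path, sep = "\t", skip = 1))
  dimnames(m) <- NULL
  structure(list(bold = m, TR = TR, params = NULL), class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("BOLD series: %d regions x %d volumes, TR = %g s\n",
              nrow(x$bold), ncol(x$bold), x$TR))
  invisible(x)
}
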