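#' Synthetic structural connectome
#'
#' Stands in for a tractography-derived connectome: regions are placed
#' uniformly on a sphere (cortical shell), weights follow an exponential
#' distance rule with multiplicative lognormal jitter (giving the heavy
#' tail typical of max-normalised fibre-count matrices), the weakest
#' entries are removed down to the requested density, and the result is
#' symmetrised and max-normalised.  Fibre lengths are the Euclidean
#' distances.
#'
#' @param n_regions Number of regions.
#' @param seed RNG seed (the generator is a pure function of its arguments
#'   and this seed).
#' @param density Fraction of region pairs retained.
#' @param length_scale_mm Exponential decay length of the distance kernel.
#' @param jitter_sdlog Standard deviation of the lognormal weight jitter
#'   (0 disables it).
#' @param radius_mm Sphere radius.
#' @param v_gl_m_per_s Signal speed used to derive the delay matrix.
#' @return List with `conn` (an [connectome()] object), `lengths_mm` and
#'   `coords` (n x 3).
#' @export
synth_connectome <- function(n_regions = 80, seed = 1, density = 0.3,
                             length_scale_mm = 40, jitter_sdlog = 0.8,
                             radius_mm = 70, v_gl_m_per_s = 20) {
  stopifnot(n_regions >= 2, density > 0, density <= 1,
            length_scale_mm > 0, radius_mm > 0)
  res <- withr::with_seed(as.integer(seed), {
    pts <- matrix(rnorm(n_regions * 3), n_regions)
    pts <- pts / sqrt(rowSums(pts^2)) * radius_mm
    dmat <- as.matrix(dist(pts))
    W <- exp(-dmat / length_scale_mm)
    if (jitter_sdlog > 0) {
      W <- W * exp(matrix(rnorm(n_regions^2, 0, jitter_sdlog), n_regions))
    }
    W[lower.tri(W)] <- t(W)[lower.tri(W)]
    diag(W) <- 0
    if (density < 1) {
      thr <- quantile(W[upper.tri(W)], 1 - density)
      W[W < thr] <- 0
    }
    dimnames(dmat) <- NULL
    list(W = W, dmat = dmat, pts = pts)
  })
  C <- process_fiber_counts(res$W)
  conn <- connectome(C, delays_from_lengths(res$dmat, v_gl_m_per_s),
                     sprintf("region_%02d", seq_len(n_regions)))
  list(conn = conn, lengths_mm = res$dmat, coords = res$pts)
}

#' Synthetic seven-network partition
#'
#' Assigns each region to one of the seven canonical resting-state
#' networks with realistic size imbalance; every network is guaranteed at
#' least one region (requires `n_regions >= 7`).
#'
#' @param n_regions Number of regions.
#' @param seed RNG seed.
#' @return An [partition()] object.
#' @export
synth_partition <- function(n_regions = 80, seed = 1) {
  stopifnot(n_regions >= 7)
  props <- c(SomMot = 0.17, Vis = 0.14, DAttn = 0.10, `Sal/VAttn` = 0.12,
             Lim = 0.08, Cont = 0.17, Def = 0.22)
  withr::with_seed(as.integer(seed), {
    sizes <- floor(props * n_regions)
    sizes[sizes < 1] <- 1
    while (sum(sizes) < n_regions) {
      k <- sample.int(7, 1)
      sizes[k] <- sizes[k] + 1L
    }
    while (sum(sizes) > n_regions) {
      big <- which(sizes > 1)
      k <- big[sample.int(length(big), 1)]
      sizes[k] <- sizes[k] - 1L
    }
    labs <- sample(rep(names(sizes), times = sizes))
    partition(labs)
  })
}

# unit-sd noise confined to the frequency bins inside [f1, f2] Hz
narrowband_noise <- function(T, TR, f1, f2) {
  freqs <- (seq_len(T) - 1) / (T * TR)
  freqs <- pmin(freqs, 1 / TR - freqs)  # two-sided
  keep <- freqs >= f1 & freqs <= f2
  if (!any(keep)) stop("no frequency bins inside the requested band")
  x <- rnorm(T)
  X <- fft(x)
  X[!keep] <- 0
  y <- Re(fft(X, inverse = TRUE) / T)
  y / sd(y)
}

#' Synthetic two-group regional BOLD data
#'
#' Emulates the group structure of the empirical arm: every subject's
#' regional signals mix one latent common narrowband (0.04-0.07 Hz) drive
#' into region-specific noise.  A subject with latent connectivity level
#' `u` uses mixing coefficient `lambda = sqrt(u)`, so the expected
#' inter-regional correlation (hence GBC) is `u` irrespective of the noise
#' spectrum.  The patient group's mean `u` is lowered by `gbc_effect`; its
#' region-noise spectrum is shifted into the analysis band (fraction
#' `nu`), which lowers phase synchrony by about `sync_effect` while
#' leaving broadband correlations - and therefore GBC - unchanged.
#'
#' @param n_controls,n_patients Group sizes.
#' @param n_regions Number of regions.
#' @param T_volumes Number of volumes per subject.
#' @param TR Repetition time (s).
#' @param gbc_effect Imposed reduction of mean GBC in the patient group.
#' @param sync_effect Imposed reduction of mean Kuramoto R in patients.
#' @param seed Master seed; per-subject seeds are derived from it and
#'   recorded in the output.
#' @param gbc_mean Mean latent GBC of the control group.
#' @param gbc_sd Between-subject standard deviation of the latent GBC.
#' @param nu_control In-band fraction of the region-noise variance for
#'   controls.
#' @param band Analysis band (Hz).
#' @return List with `controls` and `patients` (lists of `bold_series`),
#'   `subject_table` (tibble with group, subject seed, latent u, nu) and
#'   the generator settings.
#' @export
synth_bold_groups <- function(n_controls = 43, n_patients = 38,
                              n_regions = 80, T_volumes = 145, TR = 2,
                              gbc_effect = 0.11, sync_effect = 0.12,
                              seed = 1, gbc_mean = 0.40, gbc_sd = 0.16,
                              nu_control = 0.5, band = c(0.04, 0.07)) {
  stopifnot(n_controls >= 1, n_patients >= 1, n_regions >= 2,
            T_volumes >= 8, TR > 0, gbc_mean > 0, gbc_mean <= 1,
            gbc_sd >= 0, nu_control > 0, nu_control <= 1)
  u_c <- gbc_mean
  u_p <- max(0.03, gbc_mean - gbc_effect)
  lam_c <- sqrt(u_c)
  lam_p <- sqrt(u_p)
  # phase-synchrony model: R ~ lambda / sqrt(lambda^2 + (1-lambda^2) nu);
  # solve the patient in-band noise fraction for the target R reduction
  R_c <- lam_c / sqrt(lam_c^2 + (1 - lam_c^2) * nu_control)
  R_p <- max(0.05, R_c - sync_effect)
  nu_p <- lam_p^2 * (1 / R_p^2 - 1) / (1 - lam_p^2)
  nu_p <- min(1, max(0.02, nu_p))

  subj_seeds <- withr::with_seed(as.integer(seed),
    sample.int(.Machine$integer.max, n_controls + n_patients))

  gen_subject <- function(sseed, u_group, nu) {
    withr::with_seed(sseed, {
      u <- min(1, max(0.02, rnorm(1, u_group, gbc_sd)))
      lam <- sqrt(u)
      g <- narrowband_noise(T_volumes, TR, band[1], band[2])
      x <- matrix(NA_real_, n_regions, T_volumes)
      for (i in seq_len(n_regions)) {
        e_in <- narrowband_noise(T_volumes, TR, band[1], band[2])
        e_out <- narrowband_noise(T_volumes, TR, 0.009,
                                  min(band[1] - 0.006, 0.035))
        e_hi <- narrowband_noise(T_volumes, TR, band[2] + 0.006,
                                 0.45 / TR)
        e_bb <- sqrt(0.5) * e_out + sqrt(0.5) * e_hi
        noise <- sqrt(nu) * e_in + sqrt(1 - nu) * e_bb
        x[i, ] <- lam * g + sqrt(1 - lam^2) * noise
      }
      list(bold = structure(list(bold = x, TR = TR, params = NULL),
                            class = "bold_series"), u = u)
    })
  }

  controls <- patients <- list()
  us <- numeric(0)
  for (k in seq_len(n_controls)) {
    r <- gen_subject(subj_seeds[k], u_c, nu_control)
    controls[[k]] <- r$bold
    us <- c(us, r$u)
  }
  for (k in seq_len(n_patients)) {
    r <- gen_subject(subj_seeds[n_controls + k], u_p, nu_p)
    patients[[k]] <- r$bold
    us <- c(us, r$u)
  }
  subject_table <- tibble::tibble(
    group = rep(c("control", "patient"), c(n_controls, n_patients)),
    subject_seed = subj_seeds, latent_u = us,
    nu = rep(c(nu_control, nu_p), c(n_controls, n_patients)))
  list(controls = controls, patients = patients,
       subject_table = subject_table,
       settings = list(gbc_effect = gbc_effect, sync_effect = sync_effect,
                       gbc_mean = gbc_mean, gbc_sd = gbc_sd,
                       nu_control = nu_control, nu_patient = nu_p,
                       band = band, seed = seed))
}

#' Synthetic framewise-displacement table
#'
#' Gamma-distributed relative mean framewise displacement per subject with
#' a group shift for patients, emulating the head-motion summary used for
#' the motion-threshold sensitivity re-analysis.
#'
#' @param n_controls,n_patients Group sizes.
#' @param seed RNG seed.
#' @param mean_control,sd_control Moments of the control group (mm).
#' @param group_shift Added to the patient group mean (mm).
#' @return Tibble with `subject`, `group`, `fd`.
#' @export
synth_motion_table <- function(n_controls = 43, n_patients = 38, seed = 1,
                               mean_control = 0.15, sd_control = 0.09,
                               group_shift = 0.05) {
  gam <- function(n, m, s) {
    shape <- (m / s)^2
    stats::rgamma(n, shape = shape, rate = shape / m)
  }
  withr::with_seed(as.integer(seed), {
    fd <- c(gam(n_controls, mean_control, sd_control),
            gam(n_patients, mean_control + group_shift, sd_control + 0.01))
    tibble::tibble(
      subject = sprintf("sub_%03d", seq_len(n_controls + n_patients)),
      group = rep(c("control", "patient"), c(n_controls, n_patients)),
      fd = fd)
  })
}

#' Exclude subjects above a framewise-displacement threshold
#'
#' @param motion Tibble as returned by [synth_motion_table()].
#' @param threshold Exclusion threshold (subjects with `fd > threshold`
#'   are removed).
#' @return The filtered tibble; an error is raised if a group would be
#'   left empty (downstream statistics would be undefined).
#' @export
apply_motion_filter <- function(motion, threshold = 0.3) {
  stopifnot(all(c("group", "fd") %in% names(motion)))
  keep <- motion$fd <= threshold
  out <- motion[keep, , drop = FALSE]
  for (g in unique(motion$group)) {
    if (!any(out$group == g)) {
      stop(sprintf(
        "motion threshold %g excludes every subject of group '%s'; group statistics are undefined",
        threshold, g))
    }
  }
  out
}
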