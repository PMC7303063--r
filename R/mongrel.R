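# Statistic-matched image synthesis ("mongrels"): starting from seeded
# noise, alternately (a) project the pyramid bands and lowpass chain of the
# current image toward each pooling region's target statistics, blending
# overlapping per-region adjustments with the partition-of-unity pooling
# weights, and (b) reconstruct and impose the marginal statistics.  The
# result contains (approximately) the same local summary statistics as the
# target but is otherwise random.

# ---- residual bookkeeping ---------------------------------------------------

# Per-statistic scale for relative errors: dimensionless statistics
# (correlations, skewness, kurtosis) are measured on their natural O(1)
# scale; luminance-valued marginals relative to their own size with a floor
# of a tenth of the luminance range; the variance with a floor of 0.05
# (a fifth of the maximal variance of a [0,1] signal); the highpass
# variance with a 1e-3 floor.
stat_entry_scales <- function(v) {
  marg_floor <- c(mean = 0.1, var = 0.05, skew = 1, kurt = 1,
                  min = 0.1, max = 0.1)
  ne <- length(v$band_energy)
  be_floor <- rep(c(0.01, 1e-4), ne / 2)   # magnitude mean, variance
  list(marginal = pmax(abs(v$marginal), marg_floor),
       highpass_var = pmax(abs(v$highpass_var), 1e-3),
       lowpass_var = pmax(abs(v$lowpass_var), 1e-3),
       band_energy = pmax(abs(v$band_energy), be_floor),
       autocorr = rep(1, length(v$autocorr)),
       mag_acorr = rep(1, length(v$mag_acorr)),
       mag_ocorr = rep(1, length(v$mag_ocorr)),
       mag_scorr = rep(1, length(v$mag_scorr)),
       phase_scorr = rep(1, length(v$phase_scorr)))
}

STAT_GROUPS <- c("marginal", "highpass_var", "lowpass_var", "band_energy",
                 "autocorr", "mag_acorr", "mag_ocorr", "mag_scorr",
                 "phase_scorr")

# Root-mean-square scaled deviation per statistic group, pooled over
# regions.  `cur`, `tgt`: lists of stat_vectors with identical layout.
stat_group_errors <- function(cur, tgt) {
  acc <- stats::setNames(numeric(length(STAT_GROUPS)), STAT_GROUPS)
  n <- stats::setNames(numeric(length(STAT_GROUPS)), STAT_GROUPS)
  for (i in seq_along(tgt)) {
    sc <- stat_entry_scales(tgt[[i]])
    for (g in STAT_GROUPS) {
      if (!length(tgt[[i]][[g]])) next
      e <- (cur[[i]][[g]] - tgt[[i]][[g]]) / sc[[g]]
      acc[g] <- acc[g] + sum(e^2)
      n[g] <- n[g] + length(e)
    }
  }
  sqrt(acc / pmax(n, 1))
}

# ---- region precomputation --------------------------------------------------

# For every region and dyadic factor 0..S: the downsampled weight map, its
# support bounding box, the raw weight crop (for blending) and the
# normalized weight crop (for statistics).
scheme_region_pre <- function(scheme, S) {
  lapply(scheme$weights, function(w) {
    wpyr <- region_weight_pyr(w / sum(w), S)
    per_fac <- lapply(seq_len(S + 1L), function(k) {
      wf <- wpyr[[k]]
      if (is.null(wf)) return(NULL)
      bb <- bbox_of(wf)
      if (is.null(bb)) return(NULL)
      wcrop <- wf[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE]
      list(bb = bb, w = wcrop, wn = wcrop / sum(wcrop))
    })
    list(wpyr = wpyr, fac = per_fac)
  })
}

field_stats <- function(pre, rpre, config) {
  lapply(rpre, function(rp) region_stats_from_pre(pre, rp$wpyr, config))
}

# Blend per-region adjustments of a map at factor `fac` (0-based):
# out = sum_r w_r * fn(patch_r).  fn(patch, wn, i) returns the adjusted
# patch or NULL to leave the region unchanged.
region_blend <- function(map, rpre, fac, fn) {
  # weight blending must renormalize to the in-image total at this factor
  out <- map * 0
  tot <- map * 0
  for (i in seq_along(rpre)) {
    info <- rpre[[i]]$fac[[fac + 1L]]
    if (is.null(info)) next
    bb <- info$bb
    patch <- map[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE]
    adj <- fn(patch, info$wn, i)
    if (is.null(adj)) adj <- patch
    out[bb[1]:bb[2], bb[3]:bb[4]] <- out[bb[1]:bb[2], bb[3]:bb[4]] + info$w * adj
    tot[bb[1]:bb[2], bb[3]:bb[4]] <- tot[bb[1]:bb[2], bb[3]:bb[4]] + info$w
  }
  keep <- tot < 1e-9
  out[keep] <- map[keep]
  nk <- !keep
  out[nk] <- out[nk] / tot[nk]
  out
}

# Power-spectrum kernel implied by a truncated normalized autocorrelation:
# DFT of {1 at lag 0, c_d at +/-d}, evaluated on an (nr x nc) grid.
acorr_spectrum <- function(cvals, offs, nr, nc) {
  k <- matrix(0, nr, nc)
  k[1, 1] <- 1
  for (i in seq_len(nrow(offs))) {
    r1 <- (offs[i, 1] %% nr) + 1L; c1 <- (offs[i, 2] %% nc) + 1L
    r2 <- ((-offs[i, 1]) %% nr) + 1L; c2 <- ((-offs[i, 2]) %% nc) + 1L
    k[r1, c1] <- k[r1, c1] + cvals[i]
    k[r2, c2] <- k[r2, c2] + cvals[i]
  }
  Re(fft2(k))
}

# Spectral-ratio projection of one patch toward a target autocorrelation.
# Gains are derived from the spectra implied by the current and target
# truncated autocorrelations and clamped for stability.  With
# `protect_high`, gains are feathered back to 1 in the upper octave so the
# projection cannot disturb content belonging to the highpass residual.
project_patch_acorr <- function(patch, wn, c_cur, c_tgt, offs,
                                gain_clamp = c(1 / 3, 3),
                                protect_high = FALSE, beta = 1,
                                protect_from = pi) {
  nr <- nrow(patch); nc <- ncol(patch)
  if (nr < 3 || nc < 3) return(NULL)
  St <- acorr_spectrum(c_tgt, offs, nr, nc)
  Sc <- acorr_spectrum(c_cur, offs, nr, nc)
  # floors keep the truncated-spectrum estimates (which can dip negative)
  # usable in the ratio; they bound how far a single pass can attenuate
  floor_t <- 0.02 * max(abs(St)); floor_c <- 0.02 * max(abs(Sc))
  if (!is.finite(floor_c) || floor_c <= 0) return(NULL)
  G <- sqrt(pmax(St, floor_t) / pmax(Sc, floor_c))^beta
  G <- pmin(pmax(G, gain_clamp[1]), gain_clamp[2])
  if (protect_high) {
    g <- pyr_grid(nr, nc)
    keep <- 1 - radial_high(g$r, protect_from)^2
    G <- 1 + (G - 1) * keep
  }
  mu <- sum(wn * patch)
  mu + ifft2(fft2(patch - mu) * G)
}

# Fresh weighted autocorrelation of a patch treated as its own torus —
# consistent with the circular filtering the projection applies to it.
fresh_acorr <- function(p, wn, offs, h) {
  pe <- crop_wrap(p, 1L, nrow(p), 1L, ncol(p), h)
  wacorr(pe, wn, offs, h)
}

# Symmetric square root (and inverse square root) of a small correlation
# matrix, eigenvalue-floored.
corr_sqrt <- function(C, inv = FALSE, floor = 1e-4) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  v <- pmax(e$values, floor)
  p <- if (inv) -0.5 else 0.5
  e$vectors %*% diag(v^p, length(v)) %*% t(e$vectors)
}

sym_from_pairs <- function(vals, O) {
  C <- diag(O)
  i <- 0L
  for (o1 in seq_len(O - 1)) for (o2 in (o1 + 1):O) {
    i <- i + 1L
    C[o1, o2] <- C[o2, o1] <- vals[i]
  }
  C
}

# ---- marginal imposition ----------------------------------------------------

# Impose mean/variance/skewness/kurtosis (Hermite-basis adjustment fitted by
# Nelder-Mead) and then the [min, max] range.
impose_marginals <- function(x, m) {
  mu <- mean(x); sd0 <- stats::sd(as.vector(x))
  if (sd0 < 1e-12) return(x * 0 + m["mean"])
  z <- (x - mu) / sd0
  moment_gap <- function(p) {
    y <- z + p[1] * (z^2 - 1) + p[2] * (z^3 - 3 * z)
    my <- mean(y); vy <- mean((y - my)^2)
    if (vy < 1e-12) return(1e6)
    sk <- mean((y - my)^3) / vy^1.5
    ku <- mean((y - my)^4) / vy^2
    (sk - m["skew"])^2 + 0.25 * (ku - m["kurt"])^2
  }
  p <- stats::optim(c(0, 0), moment_gap, method = "Nelder-Mead",
                    control = list(maxit = 200, reltol = 1e-8))$par
  y <- z + p[1] * (z^2 - 1) + p[2] * (z^3 - 3 * z)
  # clipping to [min, max] shrinks the variance, so alternate the affine
  # mean/variance match with the range clip a few times
  for (k in 1:3) {
    my <- mean(y); vy <- stats::sd(as.vector(y))
    y <- if (vy > 1e-12) (y - my) / vy else y - my
    y <- m["mean"] + y * sqrt(max(m["var"], 0))
    y <- pmin(pmax(y, m["min"]), m["max"])
  }
  y
}

# ---- the synthesis loop -----------------------------------------------------

#' Synthesize a statistic-matched image (a "mongrel")
#'
#' Iteratively shapes seeded noise until every pooling region's summary
#' statistics approach the target field: each iteration rebuilds the
#' pyramid, projects band magnitudes toward the target autocorrelation,
#' orientation-correlation and cross-scale statistics region by region
#' (blending overlaps with the pooling weights), projects the lowpass chain
#' toward the target luminance autocorrelations while reconstructing
#' coarse-to-fine, rescales the highpass residual, and imposes the marginal
#' statistics.  Non-convergence is reported, not raised.
#'
#' @param target a `stat_field` from [compute_stat_field()].
#' @param scheme the `pooling_scheme` the target was computed under.
#' @param seed integer seed for the noise initialization.
#' @param iters maximum iterations.
#' @param tol convergence tolerance: maximum allowed relative statistic
#'   error per group (see `residual_trace` below).
#' @param source optional [lum_img()]: when given, the foveal region is
#'   constrained to the source pixels each iteration (the fovea is "seen").
#' @param progress print per-iteration residuals?
#' @return A `mongrel_result`: `image` ([lum_img()]), `residual_trace`
#'   (iterations x statistic groups; scaled RMS deviation per group, with
#'   correlations on their natural \[-1,1\] scale), `converged`, `seed`,
#'   `iterations`.
#' @export
synthesize_mongrel <- function(target, scheme, seed = 1, iters = 50,
                               tol = 0.05, source = NULL, progress = FALSE) {
  stopifnot(inherits(target, "stat_field"), inherits(scheme, "pooling_scheme"))
  prov <- target$provenance
  cfg <- prov$config
  if (!all(prov$dims == scheme$dims) ||
      !isTRUE(all.equal(prov$scheme_params[c("g", "d0", "aspect")],
                        scheme$params[c("g", "d0", "aspect")])) ||
      length(target$vectors) != length(scheme$weights))
    stop("target stat_field and pooling scheme configurations do not match",
         call. = FALSE)
  S <- cfg$S; O <- cfg$O
  offs <- acorr_offsets(cfg$M)
  half <- nrow(offs)
  dims <- prov$dims
  tgt <- target$vectors
  gm <- target$global

  rpre <- scheme_region_pre(scheme, S)
  fovea_w <- if (!is.null(source)) {
    i <- which(scheme$regions$kind == "fovea")
    if (length(i)) scheme$weights[[i[1]]] else NULL
  } else NULL

  # seeded noise matched to the global mean/variance
  x <- with_seed(seed, matrix(stats::rnorm(prod(dims), gm["mean"],
                                           sqrt(max(gm["var"], 1e-8))),
                              dims[1], dims[2]))
  x <- pmin(pmax(x, gm["min"]), gm["max"])

  trace <- matrix(NA_real_, iters, length(STAT_GROUPS),
                  dimnames = list(NULL, STAT_GROUPS))
  converged <- FALSE
  used <- 0L

  # index of the autocorr segment for chain level s (0 = luminance)
  ac_seg <- function(v, lvl) v[(lvl * half + 1):((lvl + 1) * half)]

  # Integral compensation for the variance-family statistics: the marginal
  # range clip systematically eats part of each imposed variance, so the
  # working targets are inflated by slowly-adapted per-region factors that
  # drive the measured steady-state error to zero.
  comp_lv <- lapply(tgt, function(v) rep(1, length(v$lowpass_var)))
  comp_be <- lapply(tgt, function(v) rep(1, length(v$band_energy) / 2))
  comp_hp <- rep(1, length(tgt))
  # additive bias for the correlation-type groups, same integral idea
  CORR_GROUPS <- c("autocorr", "mag_acorr", "mag_ocorr", "mag_scorr",
                   "phase_scorr")
  bias <- lapply(tgt, function(v)
    lapply(v[CORR_GROUPS], function(g) numeric(length(g))))
  comp_update <- function(cur) {
    for (i in seq_along(tgt)) {
      vt <- tgt[[i]]$lowpass_var; vc <- cur[[i]]$lowpass_var
      ok <- vt > EPS_VAR & vc > EPS_VAR
      comp_lv[[i]][ok] <<- pmin(2, pmax(0.5,
        comp_lv[[i]][ok] * (vt[ok] / vc[ok])^0.4))
      bt <- tgt[[i]]$band_energy[c(FALSE, TRUE)]
      bc <- cur[[i]]$band_energy[c(FALSE, TRUE)]
      ok <- bt > EPS_VAR & bc > EPS_VAR
      comp_be[[i]][ok] <<- pmin(2, pmax(0.5,
        comp_be[[i]][ok] * (bt[ok] / bc[ok])^0.4))
      ht <- tgt[[i]]$highpass_var; hc <- cur[[i]]$highpass_var
      if (ht > EPS_VAR && hc > EPS_VAR)
        comp_hp[i] <<- min(2, max(0.5, comp_hp[i] * (ht / hc)^0.4))
      for (g in CORR_GROUPS) {
        if (!length(tgt[[i]][[g]])) next
        b <- bias[[i]][[g]] + 0.4 * (tgt[[i]][[g]] - cur[[i]][[g]])
        bias[[i]][[g]] <<- pmin(0.25, pmax(-0.25, b))
      }
    }
  }
  # effective (compensated) correlation target for region i, group g
  tgt_eff <- function(i, g)
    pmin(1, pmax(-1, tgt[[i]][[g]] + bias[[i]][[g]]))

  # one projection pass over scales with dyadic factor >= min_fac; the
  # pixel-domain marginal stage runs only when `pixel_stage` is TRUE (the
  # refinement pass re-projects the spectral statistics after the marginal
  # remap without re-running it)
  apply_projections <- function(pyr, cur, min_fac = 0L,
                                pixel_stage = (min_fac == 0L)) {
    bands <- pyr$bands
    # ---- band-magnitude projections, coarse to fine
    for (s in rev(seq_len(S))) {
      if (s - 1L < min_fac) next
      fac <- s - 1L
      # (0) cross-scale phase nudge first (it changes both magnitude and
      # phase, so the magnitude statistics are imposed after it)
      if (s < S && O >= 1L) {
        upd <- lapply(seq_len(O), function(o)
          phase_double(upsample_band(bands[[s + 1]][[o]])))
        pidx <- (s - 1L) * O * O
        for (o in seq_len(O)) {
          re_adj <- region_blend(Re(bands[[s]][[o]]), rpre, fac, function(p, wn, i) {
            mu <- sum(wn * p); v <- sum(wn * (p - mu)^2)
            if (v < EPS_VAR) return(NULL)
            out <- p
            for (oc in seq_len(O)) {
              k <- pidx + (o - 1L) * O + oc
              d <- tgt_eff(i, "phase_scorr")[k] - cur[[i]]$phase_scorr[k]
              if (abs(d) < 1e-3) next
              bb <- rpre[[i]]$fac[[fac + 1L]]$bb
              u <- Re(upd[[oc]])[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE]
              muu <- sum(wn * u); vu <- sum(wn * (u - muu)^2)
              if (vu < EPS_VAR) next
              a <- max(-0.5, min(0.5, d)) * sqrt(v / vu)
              out <- out + a * (u - muu)
            }
            out
          })
          newb <- complex(real = re_adj, imaginary = Im(bands[[s]][[o]]))
          dim(newb) <- dim(re_adj)
          bands[[s]][[o]] <- newb
        }
      }
      mags <- lapply(seq_len(O), function(o) Mod(bands[[s]][[o]]))
      new_mags <- mags
      # (1) per-band magnitude autocorrelation
      for (o in seq_len(O)) {
        idx <- ((s - 1L) * O + o - 1L) * half
        new_mags[[o]] <- region_blend(mags[[o]], rpre, fac, function(p, wn, i) {
          # coarser scales revert more strongly through reconstruction, so
          # they get progressively stronger over-projection
          project_patch_acorr(p, wn, cur[[i]]$mag_acorr[idx + seq_len(half)],
                              tgt_eff(i, "mag_acorr")[idx + seq_len(half)], offs,
                              beta = 1.75 + 0.15 * (s - 1))
        })
      }
      # (2) first-order nudge toward cross-scale magnitude correlations
      if (s < S && s - 1L >= min_fac) {
        up <- lapply(seq_len(O), function(o) Mod(upsample_band(bands[[s + 1]][[o]])))
        sidx <- (s - 1L) * O * O
        for (o in seq_len(O)) {
          new_mags[[o]] <- region_blend(new_mags[[o]], rpre, fac, function(p, wn, i) {
            mu <- sum(wn * p); v <- sum(wn * (p - mu)^2)
            if (v < EPS_VAR) return(NULL)
            out <- p
            for (oc in seq_len(O)) {
              k <- sidx + (o - 1L) * O + oc
              d <- 1.5 * (tgt_eff(i, "mag_scorr")[k] - cur[[i]]$mag_scorr[k])
              if (abs(d) < 1e-3) next
              bb <- rpre[[i]]$fac[[fac + 1L]]$bb
              u <- up[[oc]][bb[1]:bb[2], bb[3]:bb[4], drop = FALSE]
              muu <- sum(wn * u); vu <- sum(wn * (u - muu)^2)
              if (vu < EPS_VAR) next
              a <- max(-0.5, min(0.5, d)) * sqrt(v / vu)
              out <- out + a * (u - muu)
            }
            out
          })
        }
      }
      # (3) orientation mixing toward the target cross-correlations; the
      # energy stage after it is affine, so it preserves the imposed
      # correlation structure
      if (O > 1L) {
        np <- O * (O - 1L) / 2L
        oidx <- (s - 1L) * np
        stacked <- array(unlist(new_mags), c(dims[1] %/% 2^fac,
                                             dims[2] %/% 2^fac, O))
        adj <- lapply(seq_len(O), function(o)
          region_blend(new_mags[[o]], rpre, fac, function(p, wn, i) {
            Ct <- sym_from_pairs(tgt_eff(i, "mag_ocorr")[oidx + seq_len(np)], O)
            bb <- rpre[[i]]$fac[[fac + 1L]]$bb
            Z <- sapply(seq_len(O), function(oo) {
              pp <- stacked[bb[1]:bb[2], bb[3]:bb[4], oo]
              mu <- sum(wn * pp); v <- sum(wn * (pp - mu)^2)
              if (v < EPS_VAR) return(rep(0, length(pp)))
              (pp - mu) / sqrt(v)
            })
            # fresh cross-correlation of the (already adjusted) magnitudes
            Cc <- crossprod(Z, Z * as.vector(wn))
            diag(Cc) <- pmax(diag(Cc), 1e-6)
            A <- corr_sqrt(Cc, inv = TRUE) %*% corr_sqrt(Ct)
            zo <- Z %*% A[, o]
            mu <- sum(wn * p); v <- sum(wn * (p - mu)^2)
            matrix(mu + zo * sqrt(max(v, 0)), nrow(p), ncol(p))
          }))
        new_mags <- adj
      }
      # (4) band energy last — affine map to the target mean/variance with
      # fresh in-flight measurements, so earlier stages cannot undo it
      for (o in seq_len(O)) {
        eidx <- ((s - 1L) * O + o - 1L) * 2L
        new_mags[[o]] <- region_blend(new_mags[[o]], rpre, fac, function(p, wn, i) {
          mt <- tgt[[i]]$band_energy[eidx + 1L]
          vt <- tgt[[i]]$band_energy[eidx + 2L] * comp_be[[i]][eidx / 2L + 1L]
          if (mt == 0 && vt == 0) return(NULL)
          mc <- sum(wn * p); vc <- sum(wn * (p - mc)^2)
          if (vc < EPS_VAR) return(NULL)
          mt + (p - mc) * min(4, max(0.25, sqrt(vt / vc)))
        })
      }
      # apply new magnitudes (phase preserved)
      for (o in seq_len(O)) {
        m0 <- mags[[o]]
        ratio <- pmax(new_mags[[o]], 0) / pmax(m0, 1e-12)
        ratio[m0 < 1e-12] <- 1
        bands[[s]][[o]] <- bands[[s]][[o]] * ratio
      }
    }

    # ---- lowpass chain: project autocorrelation and variance,
    # reconstructing coarse-to-fine
    hwin <- (cfg$M - 1L) %/% 2L
    chain_project <- function(lp, lvl) {
      region_blend(lp, rpre, lvl, function(p, wn, i) {
        if (all(tgt[[i]]$lowpass_var[lvl] == 0) &&
            all(ac_seg(tgt[[i]]$autocorr, lvl) == 0)) return(NULL)
        # current statistics are measured freshly from the in-flight
        # lowpass (earlier projection stages have already reshaped it);
        # the top octave belongs to the oriented bands extracted from this
        # level, whose magnitudes were just projected: protect it
        c_fresh <- fresh_acorr(p, wn, offs, hwin)
        p2 <- project_patch_acorr(p, wn, c_fresh,
                                  ac_seg(tgt_eff(i, "autocorr"), lvl), offs,
                                  protect_high = TRUE)
        if (is.null(p2)) p2 <- p
        vt <- tgt[[i]]$lowpass_var[lvl] * comp_lv[[i]][lvl]
        mu <- sum(wn * p2)
        vc <- sum(wn * (p2 - mu)^2)
        if (vc > EPS_VAR && vt > 0)
          p2 <- mu + (p2 - mu) * min(2, max(0.5, sqrt(vt / vc)))
        p2
      })
    }
    lp <- chain_project(pyr$lowpass_chain[[S]], S)
    spec <- fft2(lp)
    for (s in rev(seq_len(S))) {
      snr <- dims[1] %/% 2L^(s - 1L); snc <- dims[2] %/% 2L^(s - 1L)
      spec <- recon_level_spec(bands[[s]], spec, snr, snc, O)
      lvl <- s - 1L
      if (lvl >= max(1L, min_fac)) {
        lp <- chain_project(ifft2(spec), lvl)
        spec <- fft2(lp)
      }
    }

    # ---- highpass variance, full reconstruction, marginals
    g0 <- pyr_grid(dims[1], dims[2])
    H0 <- radial_high(g0$r, pi)
    L0 <- sqrt(pmax(0, 1 - H0^2))
    if (pixel_stage) {
      xn <- ifft2(spec * L0 + fft2(pyr$highpass) * H0)
      # luminance autocorrelation at full resolution (highpass protected,
      # current statistics measured from the in-flight image)
      xn <- region_blend(xn, rpre, 0L, function(p, wn, i) {
        project_patch_acorr(p, wn, fresh_acorr(p, wn, offs, hwin),
                            ac_seg(tgt_eff(i, "autocorr"), 0L), offs,
                            protect_high = TRUE)
      })
      xn <- impose_marginals(xn, gm)
      # highpass variance last, with fresh per-region measurements, so the
      # nonlinear marginal remap cannot disturb it; the final clip removes
      # only the (small) overshoot this surgery creates
      X <- fft2(xn)
      hp_new <- region_blend(ifft2(X * H0), rpre, 0L, function(p, wn, i) {
        vt <- tgt[[i]]$highpass_var * comp_hp[i]
        mu <- sum(wn * p); vc <- sum(wn * (p - mu)^2)
        if (vc < EPS_VAR) return(NULL)
        mu + (p - mu) * min(2, max(0.5, sqrt(vt / vc)))
      })
      xn <- ifft2(X * L0^2) + ifft2(fft2(hp_new) * H0)
      xn <- pmin(pmax(xn, gm["min"]), gm["max"])
    } else {
      # refinement tail: same fresh highpass surgery, no marginal remap
      X <- fft2(ifft2(spec * L0 + fft2(pyr$highpass) * H0))
      hp_new <- region_blend(ifft2(X * H0), rpre, 0L, function(p, wn, i) {
        vt <- tgt[[i]]$highpass_var * comp_hp[i]
        mu <- sum(wn * p); vc <- sum(wn * (p - mu)^2)
        if (vc < EPS_VAR) return(NULL)
        mu + (p - mu) * min(2, max(0.5, sqrt(vt / vc)))
      })
      xn <- ifft2(X * L0^2) + ifft2(fft2(hp_new) * H0)
      xn <- pmin(pmax(xn, gm["min"]), gm["max"])
    }
    if (!is.null(fovea_w))
      xn <- xn * (1 - fovea_w) + source$pixels * fovea_w
    xn
  }


  for (it in seq_len(iters)) {
    used <- it
    pyr <- build_pyramid(x, S = S, O = O)
    pre <- stat_precompute(pyr, cfg)
    cur <- field_stats(pre, rpre, cfg)
    trace[it, ] <- stat_group_errors(cur, tgt)
    if (progress)
      message(sprintf("iter %d: %s", it,
                      paste(sprintf("%s=%.3f", STAT_GROUPS, trace[it, ]),
                            collapse = " ")))
    if (all(trace[it, ] <= tol)) { converged <- TRUE; break }
    comp_update(cur)
    x <- apply_projections(pyr, cur, min_fac = 0L)
    # the marginal remap disturbs the just-imposed spectral statistics, so
    # each iteration ends with a refinement pass that re-projects them
    # (all scales, fresh measurements) without re-running the remap
    pyr2 <- build_pyramid(x, S = S, O = O)
    pre2 <- stat_precompute(pyr2, cfg)
    cur2 <- field_stats(pre2, rpre, cfg)
    x <- apply_projections(pyr2, cur2, min_fac = 0L, pixel_stage = FALSE)
  }
  if (!converged && used == iters) {
    # measure the state actually returned
    pyr <- build_pyramid(x, S = S, O = O)
    cur <- field_stats(stat_precompute(pyr, cfg), rpre, cfg)
    fin <- stat_group_errors(cur, tgt)
    trace <- rbind(trace, fin)
    used <- used + 1L
    converged <- all(fin <= tol)
  }

  img <- lum_img(pmin(pmax(x, 0), 1), ppd = prov$ppd, fixation = prov$fixation)
  structure(list(image = img,
                 residual_trace = trace[seq_len(used), , drop = FALSE],
                 converged = converged, seed = seed, iterations = used),
            class = "mongrel_result")
}

#' @export
print.mongrel_result <- function(x, ...) {
  fin <- x$residual_trace[nrow(x$residual_trace), ]
  cat(sprintf("<mongrel_result> %d iterations, %sconverged; worst group error %.3f (%s)\n",
              x$iterations, if (x$converged) "" else "NOT ",
              max(fin), names(fin)[which.max(fin)]))
  invisible(x)
}

#' Convenience wrapper: encode an image and synthesize its mongrel
#'
#' @param image a [lum_img()].
#' @param scheme optional `pooling_scheme` (default parameters if omitted).
#' @param config a [stat_config()].
#' @param constrain_fovea keep the original pixels in the foveal region?
#' @param ... passed to [synthesize_mongrel()].
#' @return a `mongrel_result`.
#' @export
mongrel <- function(image, scheme = NULL, config = stat_config(),
                    constrain_fovea = TRUE, ...) {
  if (is.null(scheme)) scheme <- build_pooling_scheme(image)
  target <- compute_stat_field(image, scheme, config)
  synthesize_mongrel(target, scheme,
                     source = if (constrain_fovea) image else NULL, ...)
}

#' Two mongrels of the same target: a metamer pair
#'
#' Synthesizes the target twice from different seeds and reports how far
#' apart the two images are in pixel space (RMS) versus in statistic space,
#' together with each synthesis' own residual.
#'
#' @param target a `stat_field`.
#' @param scheme the matching `pooling_scheme`.
#' @param seeds two distinct integer seeds.
#' @param ... passed to [synthesize_mongrel()].
#' @return list with `m1`, `m2` (`mongrel_result`s) and `report`
#'   (pixel_rms, stat_dist between the two syntheses' encodings,
#'   final residuals, both_converged).
#' @export
metamer_pair <- function(target, scheme, seeds = c(1, 2), ...) {
  if (length(seeds) != 2L)
    stop("`seeds` must contain two seeds", call. = FALSE)
  m1 <- synthesize_mongrel(target, scheme, seed = seeds[1], ...)
  m2 <- if (seeds[1] == seeds[2]) m1
        else synthesize_mongrel(target, scheme, seed = seeds[2], ...)
  cfg <- target$provenance$config
  f1 <- compute_stat_field(m1$image, scheme, cfg)
  f2 <- compute_stat_field(m2$image, scheme, cfg)
  err12 <- stat_group_errors(f1$vectors, f2$vectors)
  list(m1 = m1, m2 = m2,
       report = list(
         pixel_rms = sqrt(mean((m1$image$pixels - m2$image$pixels)^2)),
         stat_dist = max(err12),
         residual_1 = m1$residual_trace[nrow(m1$residual_trace), ],
         residual_2 = m2$residual_trace[nrow(m2$residual_trace), ],
         both_converged = m1$converged && m2$converged))
}
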