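# g-factor noise-amplification maps for composite GRAPPA estimation
# patterns.
#
# The analytic map propagates the acquired-sample noise exactly
# through the composite k-space-filling operator (each estimated line
# is a fixed linear combination of source samples, possibly of
# previously estimated lines), the inverse FFT, and a fixed linear
# coil combination.  Working per image column x after an inverse FFT
# along kx turns the kx kernel taps into per-x scalars, so the
# propagation reduces to small per-column matrix algebra.  The
# pseudo-multiple-replica Monte Carlo (below) is the independent
# oracle for this computation.

# hybrid-space kernel weights of one target row: matrix
# (target coil j) x (source coil c, source line index l), per x.
# tap offsets enter as phase factors exp(-2i pi d * x~ / nx).
hybrid_target_weights <- function(kernel, target_index, xtilde, nx) {
  nc <- kernel$dims$ncoils; nsrc <- kernel$dims$nsrc
  ntap <- kernel$dims$ntap
  taps <- kernel$geometry$taps
  ph <- exp(-2i * pi * taps * xtilde / nx)
  W <- matrix(0 + 0i, nc, nc * nsrc)
  tcols <- seq_len(nc) + nc * (target_index - 1L)
  for (l in seq_len(nsrc)) {
    for (c in seq_len(nc)) {
      wt <- 0 + 0i
      for (d in seq_len(ntap)) {
        wt <- wt + kernel$weights[src_col_index(nc, ntap, c, d, l), tcols] * ph[d]
      }
      W[, c + nc * (l - 1L)] <- wt
    }
  }
  W
}

# flatten plan jobs into per-target records (line, job reference,
# kind, index of the target within the job), in plan order
plan_targets <- function(plan) {
  out <- list()
  for (jb in plan$jobs) {
    for (t in seq_along(jb$lines)) {
      out <- c(out, list(list(line = jb$lines[t], r0 = jb$lines[1L],
                              kind = jb$kind, t_index = t)))
    }
  }
  out
}

#' Analytic g-factor map of a composite estimation pattern
#'
#' Computes the voxel-wise noise amplification of replacing the
#' pattern's corrupted lines by GRAPPA kernel predictions, relative to
#' the same sampling with all lines carrying their own (unamplified)
#' noise, under a fixed linear coil combination.  g = 1 everywhere for
#' an empty pattern; nontrivial patterns give g >= 1 up to numerical
#' tolerance on object pixels.
#'
#' @param plan an [build_estimation_plan()] result describing the
#'   pattern (jobs in processing order).
#' @param kernels list of kernels by kind (e.g.
#'   `list("1-AMCL" = ..., "2-AMCL" = ...)`).
#' @param combine_weights complex array `(ncoils, ny, nx)` of fixed
#'   coil-combination weights (see [rss_combine_weights()]).
#' @param sampled_lines grid ky indices carrying data (default: all
#'   acquired lines of the plan's `acquired_ky`).
#' @param noise_cov coil noise covariance (default identity).
#' @return A `gfactor_map`: `g`, `retained_snr` (= 1/g), `pattern`
#'   (estimated lines).
#' @export
compute_gfactor <- function(plan, kernels, combine_weights,
                            sampled_lines = plan$acquired_ky,
                            noise_cov = NULL) {
  dms <- dim(combine_weights)
  nc <- dms[1L]; ny <- dms[2L]; nx <- dms[3L]
  targets <- plan_targets(plan)
  tlines <- vapply(targets, `[[`, numeric(1), "line")
  for (tg in targets) {
    if (is.null(kernels[[tg$kind]])) {
      stop("pattern has unfilled lines: no kernel of kind ", tg$kind)
    }
  }
  psi_half <- NULL
  if (!is.null(noise_cov)) psi_half <- chol(noise_cov)  # upper: t(Conj(U)) %*% U = psi
  yt <- freq_index(ny)
  U <- exp(2i * pi * outer(yt, yt) / ny) / sqrt(ny)  # [y, line-as-freq]
  # column of U for grid line l: U[, l] (freq index of grid row l is yt[l])
  n_samp <- length(sampled_lines)
  base_lines <- setdiff(sampled_lines, tlines)
  g <- matrix(1, ny, nx)
  if (length(targets) == 0L) {
    return(structure(list(g = g, retained_snr = 1 / g,
                          pattern = integer(0)), class = "gfactor_map"))
  }
  xts <- freq_index(nx)
  for (x in seq_len(nx)) {
    P <- t(matrix(combine_weights[, , x], nrow = nc))   # ny x nc
    Pc <- Conj(P)
    # per-target coefficient matrices over base-sample support
    coefs <- list()     # target line -> list(lines = support, M = nc x (nc*|support|))
    for (tg in targets) {
      kern <- kernels[[tg$kind]]
      W <- hybrid_target_weights(kern, tg$t_index, xts[x], nx)
      src <- tg$r0 + kern$geometry$source_offsets
      sup <- integer(0); M <- NULL
      add_block <- function(sup, M, lines_new, blk) {
        for (i in seq_along(lines_new)) {
          l <- lines_new[i]
          j <- match(l, sup)
          cols <- seq_len(nc) + nc * (i - 1L)
          if (is.na(j)) {
            sup <- c(sup, l)
            M <- if (is.null(M)) blk[, cols, drop = FALSE] else
              cbind(M, blk[, cols, drop = FALSE])
          } else {
            mc <- seq_len(nc) + nc * (j - 1L)
            M[, mc] <- M[, mc] + blk[, cols, drop = FALSE]
          }
        }
        list(sup = sup, M = M)
      }
      for (i in seq_along(src)) {
        s <- src[i]
        wblk <- W[, seq_len(nc) + nc * (i - 1L), drop = FALSE]
        key <- as.character(s)
        if (!is.null(coefs[[key]])) {
          # source is itself an estimated line: compose
          comp <- wblk %*% coefs[[key]]$M
          res <- add_block(sup, M, coefs[[key]]$lines, comp)
        } else {
          if (!s %in% sampled_lines) {
            stop("pattern has unfilled lines: source line ", s,
                 " is neither sampled nor estimated")
          }
          res <- add_block(sup, M, s, wblk)
        }
        sup <- res$sup; M <- res$M
      }
      coefs[[as.character(tg$line)]] <- list(lines = sup, M = M)
    }
    sup_union <- sort(unique(unlist(lapply(coefs, `[[`, "lines"))))
    nS <- length(sup_union)
    G <- matrix(0 + 0i, ny, nc * nS)
    # identity passes of base lines inside the support union
    for (l in intersect(sup_union, base_lines)) {
      j <- match(l, sup_union)
      G[, seq_len(nc) + nc * (j - 1L)] <- Pc * U[, l]
    }
    # kernel contributions
    for (tg in targets) {
      cf <- coefs[[as.character(tg$line)]]
      V <- (Pc %*% cf$M) * U[, tg$line]       # ny x (nc*|sup|)
      for (i in seq_along(cf$lines)) {
        j <- match(cf$lines[i], sup_union)
        gc <- seq_len(nc) + nc * (j - 1L)
        G[, gc] <- G[, gc] + V[, seq_len(nc) + nc * (i - 1L)]
      }
    }
    if (!is.null(psi_half)) {
      for (j in seq_len(nS)) {
        gc <- seq_len(nc) + nc * (j - 1L)
        G[, gc] <- G[, gc] %*% t(psi_half)
      }
      pP <- rowSums(abs(Pc %*% t(psi_half))^2)
    } else {
      pP <- rowSums(abs(P)^2)
    }
    n_outside <- length(setdiff(base_lines, sup_union))
    var_pat <- pP * n_outside / ny + rowSums(abs(G)^2)
    var_full <- pP * n_samp / ny
    g[, x] <- sqrt(var_pat / var_full)
  }
  structure(list(g = g, retained_snr = 1 / g,
                 pattern = sort(tlines)), class = "gfactor_map")
}

#' @export
print.gfactor_map <- function(x, ...) {
  cat(sprintf("gfactor_map: %d estimated lines, g in [%.3f, %.3f]\n",
              length(x$pattern), min(x$g), max(x$g)))
  invisible(x)
}

#' Mean retained SNR (1/g) over a region of interest
#'
#' @param gmap a `gfactor_map`.
#' @param roi_mask logical matrix selecting the region (e.g. around
#'   the vessel wall).
#' @return scalar mean of `1/g` over the ROI.
#' @export
roi_mean_retained <- function(gmap, roi_mask) {
  mean(gmap$retained_snr[roi_mask])
}

# default linear reconstruction used by the Monte Carlo oracle:
# optional kernel fill of the pattern, zero-filled inverse FFT per
# coil, fixed-weight combination
replica_recon <- function(ksp, plan, kernels, combine_weights,
                          sampled_lines, ny, nx, fill) {
  nc <- dim(combine_weights)[1L]
  pos_of <- rep(NA_integer_, ny)
  pos_of[sampled_lines] <- seq_along(sampled_lines)
  if (fill) {
    for (jb in plan$jobs) {
      kern <- kernels[[jb$kind]]
      pred <- predict_job_lines(ksp, kern, jb$lines[1L], pos_of)
      for (t in seq_along(jb$lines)) {
        ksp[pos_of[jb$lines[t]], , ] <- pred[, seq_len(nc) + nc * (t - 1L)]
      }
    }
  }
  img <- matrix(0 + 0i, ny, nx)
  for (c in seq_len(nc)) {
    full <- matrix(0 + 0i, ny, nx)
    full[sampled_lines, ] <- ksp[, , c]
    img <- img + Conj(combine_weights[c, , ]) * ifft2c(full)
  }
  img
}

#' Pseudo-multiple-replica g-factor (Monte Carlo oracle)
#'
#' Reconstructs many noise-only replicas with and without kernel
#' estimation of the pattern and returns the voxel-wise ratio of the
#' reconstructed noise standard deviations.  Replicas are paired (the
#' same noise draw feeds both arms), which removes the common Monte
#' Carlo error on unaffected voxels.
#'
#' @param plan,kernels,combine_weights,sampled_lines as in
#'   [compute_gfactor()].
#' @param n_replicas number of replicas (>= 50; default 200).
#' @param noise_sd complex noise sd of the synthetic samples (> 0).
#' @param rng_seed integer seed.
#' @param recon_fn optional custom reconstruction
#'   `function(ksp, fill)` returning a complex image; default is the
#'   package's linear fill + inverse FFT + fixed combination.
#' @return A `gfactor_map` with Monte Carlo `g`.
#' @export
pseudo_replica_gfactor <- function(plan, kernels, combine_weights,
                                   sampled_lines = plan$acquired_ky,
                                   n_replicas = 200L, noise_sd = 1,
                                   rng_seed = 0L, recon_fn = NULL) {
  if (n_replicas < 50L) stop("n_replicas must be >= 50")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  dms <- dim(combine_weights)
  nc <- dms[1L]; ny <- dms[2L]; nx <- dms[3L]
  if (is.null(recon_fn)) {
    recon_fn <- function(ksp, fill) {
      replica_recon(ksp, plan, kernels, combine_weights, sampled_lines,
                    ny, nx, fill)
    }
  }
  set.seed(rng_seed)
  nl <- length(sampled_lines)
  s1 <- s2 <- matrix(0 + 0i, ny, nx)
  q1 <- q2 <- matrix(0, ny, nx)
  for (r in seq_len(n_replicas)) {
    ksp <- array(cnoise(nl * nx * nc, noise_sd), dim = c(nl, nx, nc))
    a <- recon_fn(ksp, TRUE)
    b <- recon_fn(ksp, FALSE)
    s1 <- s1 + a; q1 <- q1 + abs(a)^2
    s2 <- s2 + b; q2 <- q2 + abs(b)^2
  }
  v1 <- q1 / n_replicas - abs(s1 / n_replicas)^2
  v2 <- q2 / n_replicas - abs(s2 / n_replicas)^2
  g <- sqrt(pmax(v1, 0) / pmax(v2, .Machine$double.eps))
  structure(list(g = g, retained_snr = 1 / g,
                 pattern = sort(unlist(lapply(plan$jobs, `[[`, "lines")))),
            class = "gfactor_map")
}

#' Synthetic estimation pattern with given numbers of 1- and 2-AMCL
#' jobs
#'
#' Places `n_single` isolated lines and `n_pairs` adjacent pairs,
#' evenly spread over a ky band (default the outer part of the
#' acquired region, clear of the calibration core), with at least 3
#' clean lines between groups so no job sources another's targets.
#'
#' @param n_single number of isolated (1-AMCL) lines.
#' @param n_pairs number of adjacent (2-AMCL) pairs.
#' @param schedule a [mese_schedule()].
#' @param band ky range in which to place the pattern.
#' @return an `estimation_plan` for the pattern (equal line scores).
#' @export
make_amcl_pattern <- function(n_single, n_pairs, schedule,
                              band = NULL) {
  acq <- schedule$acquired_ky
  if (is.null(band)) band <- c(min(acq) + 4L, schedule$center_line - 12L)
  n_groups <- n_single + n_pairs
  corrupted <- rep(FALSE, length(acq))
  if (n_groups > 0L) {
    anchors <- round(seq(band[1L], band[2L], length.out = max(n_groups, 2L)))
    anchors <- anchors[seq_len(n_groups)]
    kinds <- c(rep(2L, n_pairs), rep(1L, n_single))
    for (i in seq_len(n_groups)) {
      lines <- anchors[i] + seq_len(kinds[i]) - 1L
      corrupted[match(lines, acq)] <- TRUE
    }
  }
  build_estimation_plan(corrupted, line_scores = seq_along(acq) * 0 + 1,
                        cap = n_single + 2L * n_pairs,
                        acquired_ky = acq)
}
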