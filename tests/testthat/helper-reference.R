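# Naive reference implementation of the full quantification pipeline,
# written independently with plain loops for the oracle-equivalence tests.
# It follows the same documented contracts (sampling conventions, tie
# rules, RNG protocol) but shares no code with the package internals.

ref_blur <- function(px, sigma) {
  if (sigma <= 0) return(px)
  k <- max(1L, ceiling(3 * sigma))
  t <- (-k):k
  kern <- exp(-t^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  reflect_idx <- function(n) c((k + 1):2, 1:n, (n - 1):(n - k))
  blur_1d_cols <- function(m) {
    n <- nrow(m)
    padded <- m[reflect_idx(n), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(kern)) {
      out <- out + kern[i] * padded[(i):(i + n - 1), , drop = FALSE]
    }
    out
  }
  t(blur_1d_cols(t(blur_1d_cols(px))))
}

ref_gradient <- function(px) {
  h <- nrow(px); w <- ncol(px)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  for (r in 1:h) for (cc in 2:(w - 1)) gx[r, cc] <- (px[r, cc + 1] - px[r, cc - 1]) / 2
  for (r in 2:(h - 1)) for (cc in 1:w) gy[r, cc] <- (px[r + 1, cc] - px[r - 1, cc]) / 2
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

# Gradient-direction Hough votes; returns best candidate or NULL.
# Contract: integer votes, radii scanned ascending with strict improvement,
# within a radius the first maximum in column-major order wins.
ref_hough <- function(px, radii, edge_quantile = 0.95, blur_sigma = 2) {
  h <- nrow(px); w <- ncol(px)
  g <- ref_gradient(ref_blur(px, blur_sigma))
  thr <- stats::quantile(g$mag[2:(h - 1), 2:(w - 1)], edge_quantile, names = FALSE)
  edges <- which(g$mag >= thr & g$mag > 0, arr.ind = TRUE)
  if (nrow(edges) == 0) return(NULL)
  best <- list(votes = 0L, row = NA_integer_, col = NA_integer_, radius = NA_real_)
  for (rad in radii) {
    acc <- matrix(0L, h, w)
    for (i in seq_len(nrow(edges))) {
      er <- edges[i, 1]; ec <- edges[i, 2]
      m <- g$mag[er, ec]
      uy <- g$gy[er, ec] / m; ux <- g$gx[er, ec] / m
      for (sgn in c(1, -1)) {
        vr <- round(er + sgn * rad * uy)
        vc <- round(ec + sgn * rad * ux)
        if (vr >= 1 && vr <= h && vc >= 1 && vc <= w) {
          acc[vr, vc] <- acc[vr, vc] + 1L
        }
      }
    }
    k <- which.max(acc)
    if (acc[k] > best$votes) {
      best <- list(votes = acc[k],
                   row = ((k - 1L) %% h) + 1L, col = ((k - 1L) %/% h) + 1L,
                   radius = rad, thr = thr, mag = g$mag)
    }
  }
  if (best$votes == 0L) NULL else best
}

ref_spot_score <- function(px, row, col, radius) {
  h <- nrow(px); w <- ncol(px)
  d2 <- outer((seq_len(h) - row)^2, (seq_len(w) - col)^2, `+`)
  inside <- d2 <= (0.8 * radius)^2
  ann <- d2 >= (1.2 * radius)^2 & d2 <= (1.6 * radius)^2
  if (!any(inside) || !any(ann)) return(0)
  min(max(mean(px[inside]) - mean(px[ann]), 0), 1)
}

ref_bilinear_1 <- function(px, rr, cc) {
  h <- nrow(px); w <- ncol(px)
  r0 <- min(max(floor(rr), 1), h - 1)
  c0 <- min(max(floor(cc), 1), w - 1)
  fr <- rr - floor(rr); fc <- cc - floor(cc)
  (1 - fr) * (1 - fc) * px[r0, c0] +
    (1 - fr) * fc * px[r0, c0 + 1] +
    fr * (1 - fc) * px[r0 + 1, c0] +
    fr * fc * px[r0 + 1, c0 + 1]
}

ref_rim_score <- function(mag, thr, row, col, radius) {
  hits <- c()
  for (a in 0:359) {
    th <- 2 * pi * a / 360
    rr <- row - radius * sin(th)
    cc <- col + radius * cos(th)
    if (rr >= 1 && rr <= nrow(mag) && cc >= 1 && cc <= ncol(mag)) {
      hits <- c(hits, ref_bilinear_1(mag, rr, cc) >= thr)
    }
  }
  if (length(hits) == 0) 0 else mean(hits)
}

ref_fallback_spot <- function(px, max_radius, iterations = 2L) {
  h <- nrow(px); w <- ncol(px)
  thr <- stats::quantile(px, 0.95, names = FALSE)
  if (!any(px > thr)) thr <- thr - 1 # constant image: take everything
  num_r <- 0; num_c <- 0; den <- 0
  for (r in 1:h) for (cc in 1:w) {
    if (px[r, cc] > thr) {
      num_r <- num_r + r * px[r, cc]
      num_c <- num_c + cc * px[r, cc]
      den <- den + px[r, cc]
    }
  }
  cr <- num_r / den; ccen <- num_c / den

  annular <- function(cr, ccen) {
    # midpoint-rule radius; mirrors the contract, written with tapply-free
    # accumulation
    nb <- as.integer(max_radius) + 1L
    sums <- numeric(nb); counts <- numeric(nb)
    out_sum <- 0; out_n <- 0
    dmat <- matrix(0, h, w)
    for (r in 1:h) for (cc2 in 1:w) {
      d <- sqrt((r - cr)^2 + (cc2 - ccen)^2)
      dmat[r, cc2] <- d
      if (d > max_radius) {
        out_sum <- out_sum + px[r, cc2]; out_n <- out_n + 1
      } else {
        b <- min(floor(d) + 1, nb)
        sums[b] <- sums[b] + px[r, cc2]; counts[b] <- counts[b] + 1
      }
    }
    ann <- sums / counts
    mid <- (ann[1] + out_sum / out_n) / 2
    radius <- max_radius
    for (b in seq_len(nb)) {
      if (counts[b] > 0 && ann[b] < mid) { radius <- b; break }
    }
    list(radius = radius, mid = mid, d = dmat)
  }
  est <- annular(cr, ccen)
  for (it in seq_len(iterations)) {
    sel <- est$d <= 1.5 * est$radius & px > est$mid
    if (!any(sel)) break
    den <- sum(px[sel])
    cr <- sum(row(px)[sel] * px[sel]) / den
    ccen <- sum(col(px)[sel] * px[sel]) / den
    est <- annular(cr, ccen)
  }
  list(row = cr, col = ccen, radius = est$radius)
}

ref_polar <- function(px, center, r_max, n_angles, radial_step) {
  n_radii <- floor(r_max / radial_step)
  vals <- matrix(0, n_radii, n_angles)
  for (ri in seq_len(n_radii)) {
    rho <- (ri - 0.5) * radial_step
    for (a in seq_len(n_angles)) {
      th <- 2 * pi * (a - 1) / n_angles
      vals[ri, a] <- ref_bilinear_1(px, center[1] - rho * sin(th),
                                    center[2] + rho * cos(th))
    }
  }
  vals
}

ref_smooth <- function(x, window) {
  n <- length(x); k <- (window - 1) %/% 2
  padded <- c(x[(k + 1):2], x, x[(n - 1):(n - k)])
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- mean(padded[i:(i + window - 1)])
  pmin(pmax(out, 0), 1)
}

ref_deriv <- function(x) {
  n <- length(x)
  d <- numeric(n)
  d[1] <- x[2] - x[1]; d[n] <- x[n] - x[n - 1]
  for (i in 2:(n - 1)) d[i] <- (x[i + 1] - x[i - 1]) / 2
  d
}

ref_candidates <- function(filtered, spot_hint, noise_floor, window) {
  # noise_floor may be per-bin (vector) or scalar
  d <- ref_deriv(filtered)
  n <- length(d)
  nf <- if (length(noise_floor) == 1L) rep(noise_floor, n) else noise_floor
  scan <- function(from, to, want_min) {
    if (from > to) return(NULL)
    best_i <- from; best_v <- d[from]
    if (from < to) for (i in (from + 1):to) {
      if ((want_min && d[i] < best_v) || (!want_min && d[i] > best_v)) {
        best_i <- i; best_v <- d[i]
      }
    }
    list(bin = best_i, value = best_v)
  }
  guard <- (window - 1L) %/% 2L + 1L # opposite-sign extrema need separation
  spot <- scan(1L, min(n, as.integer(floor(1.5 * spot_hint))), TRUE)
  anchor <- if (is.null(spot)) 1L else spot$bin
  vin <- scan(anchor + 1L, n, TRUE)
  anchor <- if (is.null(vin)) anchor else vin$bin
  vout <- scan(anchor + 1L + guard, n, FALSE)
  anchor <- if (is.null(vout)) anchor else vout$bin
  ring <- scan(anchor + 1L + guard, n, TRUE)
  ok <- function(e) !is.null(e) && abs(e$value) >= max(nf[e$bin], 1e-8)
  valley_ok <- ok(vin) && ok(vout)
  list(spot_edge = if (ok(spot)) spot$bin else NA_integer_,
       valley_inner = if (valley_ok) vin$bin else NA_integer_,
       valley_outer = if (valley_ok) vout$bin else NA_integer_,
       ring_outer = if (ok(ring)) ring$bin else NA_integer_)
}

ref_mode <- function(bins, bin_width) {
  if (length(bins) == 0) return(NA_real_)
  grp <- (bins - 1L) %/% bin_width
  ug <- sort(unique(grp))
  best_g <- ug[1]; best_n <- -1
  for (g in ug) {
    n <- sum(grp == g)
    if (n > best_n) { best_n <- n; best_g <- g }
  }
  best_g * bin_width + (bin_width + 1) / 2
}

# Full naive pipeline; mirrors quantify_plate's documented behavior.
ref_quantify <- function(image, config) {
  px <- image$pixels
  h <- nrow(px); w <- ncol(px)
  m <- min(h, w)

  srange <- config$spot_radius_range
  if (is.null(srange)) srange <- c(5, round(0.2 * m))
  cand <- ref_hough(px, seq(ceiling(srange[1]), floor(srange[2])))
  spot <- NULL
  if (!is.null(cand)) {
    sc <- ref_spot_score(px, cand$row, cand$col, cand$radius)
    if (sc >= config$spot_score_floor) {
      spot <- list(row = cand$row, col = cand$col, radius = cand$radius)
    }
  }
  if (is.null(spot)) spot <- ref_fallback_spot(px, floor(m / 4))

  pr <- c(ceiling(0.25 * m), floor(0.75 * m))
  pcand <- ref_hough(px, seq(pr[1], pr[2]), edge_quantile = 0.85)
  plate <- NULL
  if (!is.null(pcand) && pcand$radius >= 0.25 * m) {
    if (ref_rim_score(pcand$mag, pcand$thr, pcand$row, pcand$col,
                      pcand$radius) >= config$plate_score_floor) {
      plate <- pcand
    }
  }
  if (is.null(plate) && is.null(config$mm_per_px)) {
    stop("reference: plate edge not found")
  }
  mm_per_px <- if (is.null(config$mm_per_px)) {
    config$plate_diameter_mm / (2 * plate$radius)
  } else config$mm_per_px

  reach <- min(spot$row - 1, h - spot$row, spot$col - 1, w - spot$col)
  r_max <- reach
  if (!is.null(plate)) {
    off <- sqrt((spot$row - plate$row)^2 + (spot$col - plate$col)^2)
    r_max <- min(r_max, config$r_max_frac * (plate$radius - off))
  }
  polar <- ref_polar(px, c(spot$row, spot$col), r_max,
                     config$n_angles, config$radial_step)
  n_radii <- nrow(polar)
  spot_hint <- min(max(spot$radius / config$radial_step, 1), n_radii)

  seed_keeper <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  set.seed(config$seed)

  tail_bins <- max(8L, ceiling(config$background_frac * n_radii))
  win <- as.integer(config$smooth_window)
  win_max <- floor(n_radii / 4)
  if (win_max %% 2 == 0) win_max <- win_max - 1L
  if (win > win_max) win <- max(3L, win_max)
  one <- function(vals) {
    prof <- numeric(n_radii)
    for (ri in seq_len(n_radii)) prof[ri] <- stats::median(vals[ri, ])
    filt <- ref_smooth(prof, win)
    d <- ref_deriv(filt)
    x <- d[(n_radii - tail_bins + 1):n_radii]
    base <- config$noise_floor_k * 1.4826 * stats::median(abs(x - stats::median(x)))
    # tail-anchored floor scaled by effective angular sample count at each
    # radius (samples saturate at the annulus circumference)
    eff <- function(r) pmin(2 * pi * r, config$n_angles)
    nf <- base * sqrt(eff(n_radii - tail_bins / 2) / eff(seq_len(n_radii) - 0.5))
    nf <- pmax(nf, config$min_step / win)
    ref_candidates(filt, spot_hint, nf, win)
  }
  cands <- vector("list", config$B)
  if (config$B == 1L) {
    cands[[1]] <- one(polar)
  } else {
    for (b in seq_len(config$B)) {
      cols <- sample.int(config$n_angles, config$n_angles, replace = TRUE)
      cands[[b]] <- one(polar[, cols, drop = FALSE])
    }
  }
  if (!is.null(seed_keeper)) assign(".Random.seed", seed_keeper, envir = .GlobalEnv)

  grab <- function(f) {
    v <- integer(0)
    for (cd in cands) if (!is.na(cd[[f]])) v <- c(v, cd[[f]])
    v
  }
  bins <- list(spot_edge = grab("spot_edge"), valley_inner = grab("valley_inner"),
               valley_outer = grab("valley_outer"), ring_outer = grab("ring_outer"))
  support <- c(spot = length(bins$spot_edge) / config$B,
               valley = length(bins$valley_inner) / config$B,
               ring = length(bins$ring_outer) / config$B)
  modes <- lapply(bins, ref_mode, bin_width = config$bin_width)
  keep <- c(
    spot_edge = support[["spot"]] >= config$support_floor && !is.na(modes$spot_edge),
    valley_inner = support[["valley"]] >= config$support_floor && !is.na(modes$valley_inner),
    valley_outer = support[["valley"]] >= config$support_floor && !is.na(modes$valley_outer),
    ring_outer = support[["ring"]] >= config$support_floor && !is.na(modes$ring_outer)
  )
  if (keep[["valley_inner"]] && modes$valley_inner >= modes$valley_outer) {
    keep[["valley_inner"]] <- keep[["valley_outer"]] <- FALSE
  }
  if (keep[["spot_edge"]] && keep[["valley_inner"]] &&
      modes$spot_edge > modes$valley_inner) {
    if (support[["spot"]] < support[["valley"]]) keep[["spot_edge"]] <- FALSE
    else keep[["valley_inner"]] <- keep[["valley_outer"]] <- FALSE
  }
  if (keep[["ring_outer"]] && keep[["valley_outer"]] &&
      modes$ring_outer < modes$valley_outer) {
    keep[["ring_outer"]] <- FALSE
  }
  px_out <- c(spot_edge = NA_real_, valley_inner = NA_real_,
              valley_outer = NA_real_, ring_outer = NA_real_)
  for (f in names(px_out)) {
    if (keep[[f]]) px_out[[f]] <- (modes[[f]] - 0.5) * config$radial_step
  }
  list(px = px_out, mm = px_out * mm_per_px, support = support, B = config$B)
}
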