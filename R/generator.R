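# Synthetic-data module: seeded, ground-truth-annotated vascular bundle
# layouts, paired BF/EF renders, and balance flow traces.

# Rendered intensity levels (images live on [0, 1]).  Bright-field: bright
# lumens on a mid-gray ground with dark secondary-wall annuli; the lumen/ground
# contrast deliberately exceeds the wall/ground contrast so global Otsu
# thresholding latches onto the lumens, never the walls.
.BF_BG <- 0.45; .BF_LUMEN <- 0.95; .BF_WALL <- 0.15; .BF_FIBER <- 0.35
# Epifluorescence: dark ground, bright stained wall arcs, a faint
# autofluorescence floor on all lignified wall material, stainable fibers.
.EF_BG <- 0.05; .EF_AUTO <- 0.015; .EF_STAIN <- 0.35; .EF_FIBER <- 0.25

truth_columns <- function() {
  data.frame(id = integer(), bundle_id = integer(), x_um = numeric(),
             y_um = numeric(), type = character(), diameter_um = numeric(),
             wall_state = character(), wall_completeness = numeric(),
             expanding = logical(), conductive = logical(),
             stain_fraction = numeric(), wall_start = numeric(),
             stain_start = numeric(), stringsAsFactors = FALSE)
}

#' Construct a ground-truth vessel table by hand
#'
#' Convenience constructor (used heavily by the test-suite fixtures) that
#' validates the class invariants of ground-truth vessels: a conductive vessel
#' must carry a complete secondary wall and a stained perimeter fraction above
#' one half; an incompletely walled vessel can be neither conductive nor
#' stained above one half; vessels must not overlap.
#'
#' @param x_um,y_um vessel centre coordinates, micrometres.
#' @param diameter_um inner (lumen) diameters, micrometres.
#' @param wall_state `"full"`, `"partial"` or `"absent"`.
#' @param wall_completeness fraction of the perimeter carrying secondary wall;
#'   defaults to 1 / 0.6 / 0 for full / partial / absent.
#' @param expanding logical, immature enlarging vessel.
#' @param stain_fraction true stained fraction of the wall perimeter.
#' @param conductive logical; defaults to `wall_state == "full" &
#'   stain_fraction > 0.5`.
#' @param type `"PX"` or `"MX"`.
#' @param bundle_id integer bundle membership.
#' @param wall_start,stain_start arc start angles, radians.
#' @param wall_width wall allowance (micrometres) used in the overlap check.
#' @param fibers optional `data.frame(x_um, y_um, radius_um)` of stainable
#'   fibers attached as an attribute.
#' @return A `data.frame` of class `xylem_truth`.
#' @export
vessel_truth <- function(x_um, y_um, diameter_um, wall_state = "full",
                         wall_completeness = NULL, expanding = FALSE,
                         stain_fraction = 0.8, conductive = NULL,
                         type = "MX", bundle_id = 1L,
                         wall_start = 0, stain_start = 0,
                         wall_width = 2, fibers = NULL) {
  n <- length(x_um)
  rec <- function(x) rep_len(x, n)
  wall_state <- rec(wall_state)
  if (is.null(wall_completeness))
    wall_completeness <- c(full = 1, partial = 0.6, absent = 0)[wall_state]
  stain_fraction <- rec(stain_fraction)
  if (is.null(conductive))
    conductive <- wall_state == "full" & stain_fraction > 0.5
  tr <- data.frame(
    id = seq_len(n), bundle_id = rec(as.integer(bundle_id)),
    x_um = x_um, y_um = rec(y_um), type = rec(type),
    diameter_um = rec(diameter_um), wall_state = wall_state,
    wall_completeness = unname(rec(wall_completeness)),
    expanding = rec(expanding), conductive = rec(conductive),
    stain_fraction = stain_fraction,
    wall_start = rec(wall_start), stain_start = rec(stain_start),
    stringsAsFactors = FALSE)
  validate_truth(tr, wall_width = wall_width)
  attr(tr, "fibers") <- fibers %||%
    data.frame(x_um = numeric(), y_um = numeric(), radius_um = numeric())
  class(tr) <- c("xylem_truth", "data.frame")
  tr
}

validate_truth <- function(tr, wall_width = 2) {
  bad <- tr$conductive &
    (tr$wall_state != "full" | tr$stain_fraction <= 0.5)
  if (any(bad))
    stopf("conductive vessels must have full walls and stain fraction > 0.5 (vessel %d)",
          tr$id[which(bad)[1]])
  bad <- tr$wall_state != "full" &
    (tr$conductive | tr$stain_fraction > 0.5)
  if (any(bad))
    stopf("incompletely walled vessels cannot be conductive or stained above 0.5 (vessel %d)",
          tr$id[which(bad)[1]])
  if (any(tr$stain_fraction < 0 | tr$stain_fraction > 1))
    stopf("stain_fraction must lie in [0, 1]")
  if (nrow(tr) > 1) {
    d <- as.matrix(dist(cbind(tr$x_um, tr$y_um)))
    lim <- outer(tr$diameter_um / 2 + wall_width,
                 tr$diameter_um / 2 + wall_width, "+")
    diag(d) <- Inf
    if (any(d <= lim))
      stopf("vessels overlap (centres closer than summed radii + wall allowance)")
  }
  invisible(tr)
}

# Draw one vessel's latent class: maturity, wall state, conductivity, true
# stained fraction, and its diameter (immature vessels are either large
# expanding cells or small not-yet-lignified ones).
draw_vessel_class <- function(type, config) {
  dp <- config$diameter_params[[type]]
  d <- rlnorm(1, log(dp[1]), log(dp[2]))
  sn <- config$stain_fraction_nonconductive
  sc <- config$stain_fraction_conductive
  # diameters truncated at a biological ceiling: inflorescence-stem vessels
  # do not exceed ~30 um even when fully expanded
  if (runif(1) < config$frac_expanding) {
    if (runif(1) < 0.5) {          # expanding: enlarged, incomplete wall
      list(d = min(d * 1.5, 32), wall_state = "partial", wc = runif(1, 0.4, 0.85),
           expanding = TRUE, conductive = FALSE,
           stain = runif(1, sn[1], sn[2]))
    } else {                       # small, not yet lignified: the dye binds
      # secondary walls, so these carry at most traces of stain
      ws <- if (runif(1) < 0.5) "absent" else "partial"
      list(d = max(d * 0.6, 3), wall_state = ws,
           wc = if (ws == "absent") 0 else runif(1, 0.2, 0.6),
           expanding = FALSE, conductive = FALSE,
           stain = runif(1, sn[1], min(sn[2], 0.25)))
    }
  } else {
    fw <- config$frac_walled_nonconductive
    cond <- runif(1) >= (if (length(fw) > 1) fw[[type]] else fw)
    list(d = min(d, 30), wall_state = "full", wc = 1, expanding = FALSE,
         conductive = cond,
         stain = if (cond) runif(1, sc[1], sc[2]) else runif(1, sn[1], sn[2]))
  }
}

#' Generate the latent ground truth of one synthetic stem segment
#'
#' Places `n_bundles` collateral vascular bundles on a ring inside the image.
#' Each bundle carries a cluster of narrow protoxylem (PX) vessels on the
#' inner (pith-facing) side and a radial metaxylem (MX) file growing outward,
#' the arrangement seen in *Arabidopsis* inflorescence stems. Per-bundle
#' vessel counts are Poisson; maturity/conductivity classes follow the
#' configured fractions; vessels never overlap (slot grid plus bounded
#' rejection sampling; an infeasible request raises an error naming the
#' bundle).
#'
#' @param config an [generator_config()] object.
#' @param seed integer; defaults to `config$seed`. Identical `(config, seed)`
#'   yield identical output.
#' @return A `data.frame` of class `xylem_truth` (one row per vessel; see
#'   [vessel_truth()] for columns), with stainable fibers attached as the
#'   `"fibers"` attribute.
#' @export
build_ground_truth <- function(config, seed = config$seed) {
  validate_config(config)
  # bounded whole-segment rejection: a rare crowded draw (many vessels, some
  # at the diameter ceiling) can defeat the placement search; re-propose the
  # segment from a derived seed before declaring the configuration infeasible
  err <- NULL
  for (try in 0:4) {
    out <- tryCatch(
      build_ground_truth_once(config,
                              if (try == 0) seed
                              else child_seed(seed, 31337L + try)),
      error = function(e) e)
    if (!inherits(out, "error")) return(out)
    err <- out
  }
  stop(err)
}

build_ground_truth_once <- function(config, seed) {
  ps <- config$pixel_size
  H <- config$image_shape[1]; W <- config$image_shape[2]
  ww <- config$wall_width
  ext_x <- (W - 1) * ps; ext_y <- (H - 1) * ps
  cx <- ext_x / 2; cy <- ext_y / 2
  r_cap <- min(cx, cy) - ww - 2          # max radial reach from the centre
  with_seed(seed, {
    nb <- config$n_bundles
    rot <- runif(1, 0, 2 * pi)
    # per-segment study conditions: a shared plant-vigour factor spreads the
    # count means (stems differ strongly, metaxylem files especially), the
    # maturation state sets type-specific non-conductive fractions, and a
    # size factor scales the diameter medians
    z <- max(min(rnorm(1), 1.8), -2)  # vigour factor, truncated (a fixed field
    # of view cannot hold arbitrarily vigorous stems)
    cd <- config$count_dispersion
    g_px <- exp(cd[[1]] * z - cd[[1]]^2 / 2)
    g_mx <- exp(cd[[2]] * z - cd[[2]]^2 / 2)
    m_nc <- config$frac_walled_nonconductive
    if (length(m_nc) == 1L) m_nc <- c(PX = unname(m_nc), MX = unname(m_nc))
    nu <- config$frac_nonconductive_concentration
    q_nc <- vapply(c(PX = "PX", MX = "MX"), function(t) {
      m <- m_nc[[t]]
      if (m > 0 && is.finite(nu)) stats::rbeta(1, m * nu, (1 - m) * nu) else m
    }, numeric(1))
    config$frac_walled_nonconductive <- q_nc
    if (config$diameter_scale_cv > 0) {
      ds <- exp(rnorm(1, -config$diameter_scale_cv^2 / 2,
                      config$diameter_scale_cv))
      config$diameter_params$PX[1] <- config$diameter_params$PX[1] * ds
      config$diameter_params$MX[1] <- config$diameter_params$MX[1] * ds
    }
    sp_mx <- qlnorm(0.95, log(config$diameter_params$MX[1]),
                    log(config$diameter_params$MX[2])) + 2 * ww + 1
    # minimum centre-to-centre distance between vessels of different bundles;
    # keeps bundles resolvable by single-linkage clustering downstream
    inter_gap <- 40
    # clear radial gap between the PX cluster edge and the first MX vessel;
    # larger than any intra-group clearance, so the inner/outer type split is
    # unambiguous
    px_mx_gap <- 10
    lat_max <- if (nb > 1) max(12, pi * config$ring_radius / nb - 20) else 45

    nmax <- 4L * (config$px_count_mean + config$mx_count_mean + 10L)
    px <- py <- pre <- numeric(nmax)     # placed centres + effective radii
    pbundle <- integer(nmax)
    V <- list(type = character(nmax), d = numeric(nmax),
              wall_state = character(nmax), wc = numeric(nmax),
              expanding = logical(nmax), conductive = logical(nmax),
              stain = numeric(nmax), wall_start = numeric(nmax),
              stain_start = numeric(nmax))
    fx <- fy <- fr <- numeric(0)        # accepted fibers
    vid <- 0L

    # vectorized screening of candidate centres against bounds, same-bundle
    # packing clearance, and the inter-bundle separation
    first_clear <- function(X, Y, re, b) {
      ok <- X - re >= 1 & X + re <= ext_x - 1 &
        Y - re >= 1 & Y + re <= ext_y - 1
      if (vid > 0 && any(ok)) {
        i <- seq_len(vid)
        same <- i[pbundle[i] == b]; other <- i[pbundle[i] != b]
        if (length(X) == 1L) {
          if (ok && length(same)) {
            d2 <- (px[same] - X)^2 + (py[same] - Y)^2
            ok <- all(d2 > (pre[same] + re + 0.5)^2)
          }
          if (ok && length(other)) {
            d2 <- (px[other] - X)^2 + (py[other] - Y)^2
            ok <- all(d2 > inter_gap^2)
          }
        } else {
          m <- length(X)
          if (length(same)) {
            D2 <- (X - rep(px[same], each = m))^2 +
              (Y - rep(py[same], each = m))^2
            dim(D2) <- c(m, length(same))
            ok <- ok & rowSums(D2 <= rep((pre[same] + re + 0.5)^2,
                                         each = m)) == 0
          }
          if (length(other)) {
            D2 <- (X - rep(px[other], each = m))^2 +
              (Y - rep(py[other], each = m))^2
            dim(D2) <- c(m, length(other))
            ok <- ok & rowSums(D2 <= inter_gap^2) == 0
          }
        }
      }
      which(ok)[1]
    }
    add_vessel <- function(b, type, cl, x, y, re) {
      vid <<- vid + 1L
      px[vid] <<- x; py[vid] <<- y; pre[vid] <<- re; pbundle[vid] <<- b
      V$type[vid] <<- type; V$d[vid] <<- cl$d
      V$wall_state[vid] <<- cl$wall_state; V$wc[vid] <<- cl$wc
      V$expanding[vid] <<- cl$expanding; V$conductive[vid] <<- cl$conductive
      V$stain[vid] <<- cl$stain
      V$wall_start[vid] <<- runif(1, 0, 2 * pi)
      V$stain_start[vid] <<- runif(1, 0, 2 * pi)
    }

    for (b in seq_len(nb)) {
      alpha <- rot + 2 * pi * (b - 1) / nb
      u <- c(cos(alpha), sin(alpha)); v <- c(-sin(alpha), cos(alpha))
      n_px <- rpois(1, config$px_count_mean * g_px / nb)
      n_mx <- rpois(1, config$mx_count_mean * g_mx / nb)
      at <- function(radial, lateral)
        c(cx + radial * u[1] + lateral * v[1],
          cy + radial * u[2] + lateral * v[2])

      # --- PX cluster: compact greedy packing around the ring radius,
      # filling laterally before growing radially (keeps the cluster a
      # shallow band so the PX-MX axis gap stays the dominant one)
      interleave <- function(lim, by) {
        s <- seq(0, lim, by = by)
        c(0, as.vector(rbind(s[-1], -s[-1])))
      }
      make_grid <- function(rad_lim, lat_lim) {
        rad_off <- interleave(rad_lim, 2)
        lat_off <- interleave(lat_lim, 2)
        list(rad = rep(rad_off, each = length(lat_off)),
             lat = rep(lat_off, times = length(rad_off)))
      }
      # second, wider pass is the safety valve for crowded count draws
      grids <- list(make_grid(60, lat_max), make_grid(110, lat_max + 14))
      chunk <- 120L
      px_outer <- config$ring_radius      # outermost PX edge, tracks growth
      for (k in seq_len(n_px)) {
        cl <- draw_vessel_class("PX", config)
        re <- cl$d / 2 + ww
        hit_rad <- NA_real_
        for (g in grids) {
          ncand <- length(g$rad)
          for (s in seq(1L, ncand, by = chunk)) {
            j <- s:min(s + chunk - 1L, ncand)
            radial <- config$ring_radius + g$rad[j] + runif(length(j), -1, 1)
            lateral <- g$lat[j] + runif(length(j), -1, 1)
            X <- cx + radial * u[1] + lateral * v[1]
            Y <- cy + radial * u[2] + lateral * v[2]
            i <- first_clear(X, Y, re, b)
            if (!is.na(i)) {
              hit_rad <- g$rad[j[i]]
              add_vessel(b, "PX", cl, X[i], Y[i], re)
              px_outer <- max(px_outer, config$ring_radius + hit_rad + re)
              break
            }
          }
          if (!is.na(hit_rad)) break
        }
        if (is.na(hit_rad))
          stopf("vessel placement infeasible in bundle %d (PX cluster)", b)
      }

      # --- MX radial file marching outward from just beyond the PX cluster,
      # spilling into flanking columns when a column is radially full or a
      # link would break the chain
      chain_base <- px_outer + px_mx_gap
      col_off <- c(0, 1, -1, 2, -2, 3, -3) * 0.9 * sp_mx
      ncols <- length(col_off)
      cur <- rep(chain_base, ncols)         # per-column growth front
      prevc <- rep(NA_real_, ncols); prevr <- rep(NA_real_, ncols)
      for (k in seq_len(n_mx)) {
        cl <- draw_vessel_class("MX", config)
        re <- cl$d / 2 + ww
        ok <- FALSE
        for (ci in seq_len(ncols)) {
          for (attempt in 1:40) {
            cand <- cur[ci] + re + runif(1, 0, 2)
            # keep every chain link below the downstream bundle-clustering
            # cut (no fragments) and every within-chain clearance below the
            # radial PX-MX gap (no spurious split points)
            if (cand + re > r_cap ||
                (!is.na(prevc[ci]) &&
                 (cand - prevc[ci] > 32 ||
                  cand - prevc[ci] - prevr[ci] - re > 6))) break
            p <- at(cand, col_off[ci] + runif(1, -3, 3))
            if (!is.na(first_clear(p[1], p[2], re, b))) {
              ok <- TRUE; break
            }
            cur[ci] <- cur[ci] + 2   # slide outward within this column
          }
          if (ok) {
            cur[ci] <- cand + re + 1; prevc[ci] <- cand; prevr[ci] <- re
            break
          }
        }
        if (!ok) {
          # catch-all for crowded draws: bounded scan over the bundle's
          # outward sector
          lat_grid <- seq(-48, 48, by = 3)
          rad_grid <- seq(chain_base, r_cap, by = 3)
          rads <- rep(rad_grid, each = length(lat_grid))
          lats <- rep(lat_grid, times = length(rad_grid))
          for (s in seq(1L, length(rads), by = 160L)) {
            j <- s:min(s + 159L, length(rads))
            radial <- rads[j] + runif(length(j), -1, 1)
            lateral <- lats[j] + runif(length(j), -1, 1)
            X <- cx + radial * u[1] + lateral * v[1]
            Y <- cy + radial * u[2] + lateral * v[2]
            i <- first_clear(X, Y, re, b)
            if (!is.na(i)) {
              p <- c(X[i], Y[i]); ok <- TRUE
              break
            }
          }
        }
        if (!ok) stopf("vessel placement infeasible in bundle %d (MX file)", b)
        add_vessel(b, "MX", cl, p[1], p[2], re)
      }

      # --- stainable fibers flanking the PX cluster (confounder texture);
      # kept clear of every vessel's measurement annulus
      if (n_px + n_mx > 0 && config$fiber_density > 0) {
        n_f <- rpois(1, config$fiber_density)
        for (k in seq_len(n_f)) {
          rf <- runif(1, 0.8, 1.6)
          radial <- config$ring_radius + runif(40, -30, 15)
          lateral <- runif(40, -lat_max - 10, lat_max + 10)
          X <- cx + radial * u[1] + lateral * v[1]
          Y <- cy + radial * u[2] + lateral * v[2]
          ok <- X - rf >= 1 & X + rf <= ext_x - 1 &
            Y - rf >= 1 & Y + rf <= ext_y - 1
          if (vid > 0) {
            i <- seq_len(vid)
            D2 <- (X - rep(px[i], each = 40L))^2 +
              (Y - rep(py[i], each = 40L))^2
            dim(D2) <- c(40L, vid)
            ok <- ok & rowSums(D2 <= rep((pre[i] + rf + 1.2)^2,
                                         each = 40L)) == 0
          }
          hit <- which(ok)[1]
          if (!is.na(hit)) {
            fx <- c(fx, X[hit]); fy <- c(fy, Y[hit]); fr <- c(fr, rf)
          }
        }
      }
    }

    tr <- if (vid > 0) {
      data.frame(id = seq_len(vid), bundle_id = pbundle[seq_len(vid)],
                 x_um = px[seq_len(vid)], y_um = py[seq_len(vid)],
                 type = V$type[seq_len(vid)],
                 diameter_um = V$d[seq_len(vid)],
                 wall_state = V$wall_state[seq_len(vid)],
                 wall_completeness = V$wc[seq_len(vid)],
                 expanding = V$expanding[seq_len(vid)],
                 conductive = V$conductive[seq_len(vid)],
                 stain_fraction = V$stain[seq_len(vid)],
                 wall_start = V$wall_start[seq_len(vid)],
                 stain_start = V$stain_start[seq_len(vid)],
                 stringsAsFactors = FALSE)
    } else truth_columns()
    attr(tr, "fibers") <- data.frame(x_um = fx, y_um = fy, radius_um = fr)
    class(tr) <- c("xylem_truth", "data.frame")
    validate_truth(tr, wall_width = ww)
    tr
  })
}

#' Render the paired bright-field / epifluorescence images of a segment
#'
#' Bright-field channel: bright lumen discs on a mid-gray ground with dark
#' secondary-wall annuli whose angular extent equals the wall completeness.
#' Epifluorescence channel: dark ground, a faint autofluorescence floor over
#' all wall material, bright stained arcs of angular extent
#' `stain_fraction * 360` degrees, and faint fiber speckle near the PX
#' clusters. Both channels are convolved with a Gaussian PSF, Gaussian noise
#' is added (seeded from `config$seed`, so identical config + seed give
#' bit-identical images), and intensities are quantized to the 16-bit grid so
#' TIFF round trips are exact.
#'
#' @param truth an `xylem_truth` table (may be empty).
#' @param config the matching [generator_config()].
#' @return An [image_pair()] object.
#' @export
render_pair <- function(truth, config) {
  validate_config(config)
  ps <- config$pixel_size
  H <- config$image_shape[1]; W <- config$image_shape[2]
  ww <- config$wall_width
  bf <- matrix(.BF_BG, H, W)
  ef <- matrix(.EF_BG, H, W)

  paint <- function(x_um, y_um, r_out, fn) {
    # fn(dist, ang, sub_bf, sub_ef) -> list(bf, ef); patch-local painter
    r0 <- floor((y_um - r_out) / ps) - 1; r1 <- ceiling((y_um + r_out) / ps) + 3
    c0 <- floor((x_um - r_out) / ps) - 1; c1 <- ceiling((x_um + r_out) / ps) + 3
    rr <- max(1, r0):min(H, r1); cc <- max(1, c0):min(W, c1)
    dy <- (rr - 1) * ps - y_um; dx <- (cc - 1) * ps - x_um
    dist <- sqrt(outer(dy^2, dx^2, "+"))
    ang <- atan2(matrix(dy, length(rr), length(cc)),
                 matrix(dx, length(rr), length(cc), byrow = TRUE)) %% (2 * pi)
    res <- fn(dist, ang, bf[rr, cc, drop = FALSE], ef[rr, cc, drop = FALSE])
    bf[rr, cc] <<- res$bf; ef[rr, cc] <<- res$ef
  }

  for (i in seq_len(nrow(truth))) {
    vs <- truth[i, ]
    r_l <- vs$diameter_um / 2
    r_o <- r_l + ww
    if (vs$x_um - r_o < 0 || vs$x_um + r_o > (W - 1) * ps ||
        vs$y_um - r_o < 0 || vs$y_um + r_o > (H - 1) * ps)
      stopf("vessel %d extends outside the image bounds", vs$id)
    paint(vs$x_um, vs$y_um, r_o, function(dist, ang, sbf, sef) {
      lum <- dist <= r_l
      annulus <- dist > r_l & dist <= r_o
      wall_arc <- annulus & in_arc(ang, vs$wall_start,
                                   vs$wall_completeness * 2 * pi)
      stain_arc <- annulus & in_arc(ang, vs$stain_start,
                                    vs$stain_fraction * 2 * pi)
      sbf[lum] <- .BF_LUMEN
      sbf[wall_arc] <- .BF_WALL
      sef[wall_arc] <- pmax(sef[wall_arc], .EF_BG + .EF_AUTO)
      sef[stain_arc] <- .EF_BG + .EF_STAIN
      list(bf = sbf, ef = sef)
    })
  }

  fib <- attr(truth, "fibers")
  for (i in seq_len(NROW(fib))) {
    f <- fib[i, ]
    paint(f$x_um, f$y_um, f$radius_um, function(dist, ang, sbf, sef) {
      m <- dist <= f$radius_um
      sbf[m] <- .BF_FIBER
      sef[m] <- .EF_BG + .EF_FIBER
      list(bf = sbf, ef = sef)
    })
  }

  if (config$psf_sigma > 0) {
    sig <- config$psf_sigma / ps
    bf <- EBImage::imageData(EBImage::gblur(EBImage::Image(bf), sigma = sig))
    ef <- EBImage::imageData(EBImage::gblur(EBImage::Image(ef), sigma = sig))
  }
  if (config$noise_sd > 0) {
    with_seed(child_seed(config$seed, 999L), {
      bf <- bf + rnorm(length(bf), 0, config$noise_sd)
      ef <- ef + rnorm(length(ef), 0, config$noise_sd)
    })
  }
  bf <- round(pmin(pmax(bf, 0), 1) * 65535) / 65535
  ef <- round(pmin(pmax(ef, 0), 1) * 65535) / 65535
  image_pair(bf, ef, ps)
}

#' Synthesize a cumulative-mass balance trace for a known conductivity
#'
#' The steady volumetric flow follows from the experimental conductivity via
#' `F = Kh * dP / L`; mass accumulates at `F * density`, optionally through an
#' initial exponential transient, and each balance reading carries additive
#' Gaussian noise.
#'
#' @param true_kh experimental hydraulic conductivity, m^4 MPa^-1 s^-1.
#' @param config an [generator_config()] (supplies dP, L, density, sampling).
#' @param seed integer noise seed.
#' @return A [flow_trace()] object sampled at `0, dt, ..., duration` seconds.
#' @export
synthesize_flow_trace <- function(true_kh, config, seed = config$seed) {
  validate_config(config)
  if (!is_number(true_kh) || true_kh <= 0) stopf("true_kh must be > 0")
  if (config$duration < 3 * config$sampling_interval)
    stopf("duration must cover at least 3 sampling intervals")
  t <- seq(0, config$duration, by = config$sampling_interval)
  flow_m3s <- true_kh * config$pressure_gradient / config$segment_length
  rate_gs <- flow_m3s * config$water_density * 1000
  tau <- config$transient_tau
  m <- if (tau > 0) rate_gs * (t - tau * (1 - exp(-t / tau))) else rate_gs * t
  if (config$balance_noise_sd > 0)
    m <- m + with_seed(seed, rnorm(length(t), 0, config$balance_noise_sd))
  flow_trace(t, m, config$pressure_gradient, config$segment_length,
             config$water_density)
}

# Calibrate the pre-truncation (meanlog, sdlog) so that the lognormal
# truncated to (0, 1] has exactly the configured mean and CV: the configured
# values describe the delivered per-segment efficiency ratio, which by
# definition cannot exceed 1.
calibrate_efficiency <- function(mean, cv) {
  mean <- as.numeric(mean); cv <- as.numeric(cv)
  # truncated raw moments: E[X^k | X <= 1]
  tmom <- function(mu, sigma, k)
    exp(k * mu + k^2 * sigma^2 / 2) *
    pnorm((-mu - k * sigma^2) / sigma) / pnorm(-mu / sigma)
  obj <- function(p) {
    m1 <- tmom(p[1], exp(p[2]), 1)
    m2 <- tmom(p[1], exp(p[2]), 2)
    cv_t <- sqrt(pmax(m2 - m1^2, 0)) / m1
    (m1 - mean)^2 + (cv_t - cv)^2
  }
  start <- c(log(mean) - log(1 + cv^2) / 2, log(sqrt(log(1 + cv^2))))
  p <- stats::optim(start, obj, method = "Nelder-Mead",
                    control = list(reltol = 1e-14, maxit = 2000))$par
  c(meanlog = p[1], sdlog = exp(p[2]))
}

draw_efficiency <- function(pars, n = 1) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (k in 1:10000) {
      x <- rlnorm(1, pars[["meanlog"]], pars[["sdlog"]])
      if (x <= 1) break
    }
    out[i] <- x
  }
  out
}

#' Generate a cohort of paired apical and basal synthetic segments
#'
#' One apical and one basal segment per plant, mirroring the two segments cut
#' from each inflorescence stem. For each segment a true efficiency
#' `e = Kh / Kht` is drawn from the configured truncated lognormal, the
#' experimental conductivity is set to `e * Kht(true conductive vessels)`, and
#' a balance trace is synthesized. Child seeds derive deterministically from
#' `seed`, so a cohort is reproducible as a whole.
#'
#' @param n_plants number of plants (>= 1); yields `2 * n_plants` segments.
#' @param config_apical,config_basal generator configs for the two positions.
#' @param seed master seed.
#' @param render if `FALSE`, skip image rendering (`image_pair = NULL`);
#'   ground truth, conductivities, and flow traces are still produced. Used
#'   for large statistical replications where the image path is not under
#'   study.
#' @return A list of `xylem_segment` objects with elements `plant`,
#'   `segment_type`, `truth`, `image_pair`, `flow_trace`, `true_kht`,
#'   `true_kh`, `efficiency`, `config`.
#' @export
generate_cohort <- function(n_plants,
                            config_apical = generator_config("apical"),
                            config_basal = generator_config("basal"),
                            seed = 1L, render = TRUE) {
  if (!is_count(n_plants) || n_plants < 1) stopf("n_plants must be >= 1")
  validate_config(config_apical); validate_config(config_basal)
  eff <- list(
    apical = calibrate_efficiency(config_apical$efficiency_params[1],
                                  config_apical$efficiency_params[2]),
    basal = calibrate_efficiency(config_basal$efficiency_params[1],
                                 config_basal$efficiency_params[2]))
  segs <- vector("list", 2L * n_plants)
  k <- 0L
  for (i in seq_len(n_plants)) {
    for (st in c("apical", "basal")) {
      cfg <- if (st == "apical") config_apical else config_basal
      cfg$seed <- child_seed(seed, 2L * i + (st == "basal"))
      truth <- build_ground_truth(cfg, cfg$seed)
      true_kht <- compute_kht(truth$diameter_um[truth$conductive])
      e <- with_seed(child_seed(cfg$seed, 5L), draw_efficiency(eff[[st]]))
      true_kh <- e * true_kht
      trace <- if (true_kh > 0)
        synthesize_flow_trace(true_kh, cfg, child_seed(cfg$seed, 6L)) else NULL
      pair <- if (render) render_pair(truth, cfg) else NULL
      # invariant: the stored theoretical conductivity is the Hagen-Poiseuille
      # sum over the truly conductive vessels
      stopifnot(true_kht == 0 ||
                  abs(true_kht - compute_kht(truth$diameter_um[truth$conductive])) <=
                  1e-12 * true_kht,
                true_kh <= true_kht)
      k <- k + 1L
      segs[[k]] <- structure(
        list(plant = i, segment_type = st, truth = truth, image_pair = pair,
             flow_trace = trace, true_kht = true_kht, true_kh = true_kh,
             efficiency = e, config = cfg),
        class = "xylem_segment")
    }
  }
  segs
}

#' @export
print.xylem_segment <- function(x, ...) {
  cat(sprintf("<xylem_segment> plant %d, %s: %d vessels (%d conductive), Kht %.3e, Kh %.3e m^4 MPa^-1 s^-1%s\n",
              x$plant, x$segment_type, nrow(x$truth), sum(x$truth$conductive),
              x$true_kht, x$true_kh,
              if (is.null(x$image_pair)) " [not rendered]" else ""))
  invisible(x)
}
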