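# Classification module: the two conductivity criteria and xylem-type
# assignment.

#' Bright-field conductivity call
#'
#' A vessel counts as conductive in bright field when its secondary cell wall
#' is fully developed — operationalized as wall completeness of at least
#' `theta_bf` — and it is not an expanding (immature) vessel.
#'
#' @param wall_completeness fraction(s) in \[0, 1\].
#' @param expanding logical(s).
#' @param theta_bf completeness threshold in (0, 1\]; default 0.9.
#' @return Logical vector.
#' @export
classify_bf <- function(wall_completeness, expanding, theta_bf = 0.9) {
  if (!is_number(theta_bf) || theta_bf <= 0 || theta_bf > 1)
    stopf("theta_bf must lie in (0, 1]")
  if (any(wall_completeness < 0 | wall_completeness > 1, na.rm = TRUE))
    stopf("wall_completeness must lie in [0, 1]")
  wall_completeness >= theta_bf & !expanding
}

#' Epifluorescence conductivity call
#'
#' A vessel counts as conductive when more than one half of its secondary
#' wall perimeter is stained: strictly `stain_fraction > 0.5`.
#'
#' @param stain_fraction fraction(s) in \[0, 1\].
#' @return Logical vector.
#' @export
classify_ef <- function(stain_fraction) {
  if (any(stain_fraction < 0 | stain_fraction > 1, na.rm = TRUE))
    stopf("stain_fraction must lie in [0, 1]")
  stain_fraction > 0.5
}

#' Flag expanding (immature, enlarging) vessels
#'
#' The quantitative stand-in for the visual identification of expanding
#' vessel cells: a vessel is flagged when its wall is incomplete
#' (`wall_completeness < theta_bf`) and its lumen area exceeds the `q`-th
#' percentile of the unwalled vessels in the same image — expanding cells are
#' the large thin-walled ones, while small unwalled vessels are simply not
#' yet lignified.
#'
#' @param records vessel table with `wall_completeness` and `area_um2`.
#' @param theta_bf wall-completeness threshold (default 0.9).
#' @param q percentile (0-100) among unwalled vessels; default 50.
#' @return Logical vector along the rows of `records`.
#' @export
flag_expanding <- function(records, theta_bf = 0.9, q = 50) {
  unwalled <- records$wall_completeness < theta_bf
  if (!any(unwalled)) return(rep(FALSE, nrow(records)))
  cut <- quantile(records$area_um2[unwalled], q / 100, names = FALSE)
  unwalled & records$area_um2 > cut
}

# Exact largest-gap split of one bundle along its inner->outer axis.
# Returns list(type = "PX"/"MX" per member, boundary = split position in
# pith-distance units (NA when the split is not trustworthy), gap = the
# radial clearance at the split.
split_bundle_types <- function(pos, diam, px_diameter_cutoff) {
  n <- length(pos)
  if (n < 2)
    return(list(type = ifelse(diam < px_diameter_cutoff, "PX", "MX"),
                boundary = NA_real_, gap = NA_real_))
  o <- order(pos)
  r <- diam / 2
  # radial clearance between consecutive vessels (edge to edge)
  gaps <- (pos[o][-1] - r[o][-1]) - (pos[o][-n] + r[o][-n])
  cands <- which(gaps == max(gaps))
  if (length(cands) > 1) {
    # tie: prefer the split whose inner group has the smaller mean diameter
    inner_mean <- vapply(cands, function(k) mean(diam[o][1:k]), numeric(1))
    cands <- cands[which.min(inner_mean)]
  }
  k <- cands[1]
  type <- rep("MX", n)
  type[o[1:k]] <- "PX"
  # sanity: protoxylem is the narrow inner group; if the "inner" group is the
  # wider one the cluster shows no PX/MX contrast along the axis
  if (mean(diam[o][1:k]) >= mean(diam[o][(k + 1):n]))
    return(list(type = rep(NA_character_, n), boundary = NA_real_,
                gap = max(gaps)))
  boundary <- mean(c(pos[o][k] + r[o][k], pos[o][k + 1] - r[o][k + 1]))
  list(type = type, boundary = boundary, gap = max(gaps))
}

#' Assign xylem type (protoxylem vs metaxylem) to each vessel
#'
#' Vessels are grouped into bundles (given `bundle_id`, or by single-linkage
#' clustering of centroids cut at `bundle_gap_um`). In a multi-bundle section
#' each vessel's inner-to-outer coordinate is its distance from the pith
#' (estimated as the unweighted mean of bundle centroids); an isolated
#' bundle uses the first principal direction of its centroids instead,
#' oriented so diameters increase outward. Each cluster is split at the
#' largest radial clearance between consecutive vessels: the inner group is
#' the protoxylem (PX) cluster, everything outward is metaxylem (MX;
#' secondary xylem is pooled with MX). A split is trusted when the cluster
#' has at least five vessels, the clearance at the split is substantial
#' (>= 8 um) and the inner group is the narrower one; clusters failing these
#' checks — detached chain fragments, pure-PX or pure-MX groups — are typed
#' against the boundary of the nearest trusted cluster, which is almost
#' always their parent bundle. With no trusted cluster at all, each cluster
#' falls back to its own split and isolated vessels to a diameter cutoff.
#'
#' @param records vessel table with `centroid_x_um`, `centroid_y_um`,
#'   `diameter_um`, and optionally `bundle_id`.
#' @param bundle_gap_um single-linkage cut height for bundle clustering
#'   (micrometres, default 34).
#' @param px_diameter_cutoff fallback diameter (um) below which an isolated
#'   vessel counts as PX; default 8.
#' @param pith_center optional `c(x, y)` um; defaults to the
#'   `"pith_center_um"` attribute of `records` (attached by
#'   [measure_vessels()]: the pith sits at the section centre) and, failing
#'   that, to the unweighted mean of cluster centroids.
#' @return Character vector, `"PX"` or `"MX"`, along the rows of `records`.
#' @export
assign_xylem_type <- function(records, bundle_gap_um = 34,
                              px_diameter_cutoff = 8, pith_center = NULL) {
  n <- nrow(records)
  if (n == 0) return(character(0))
  cent <- cbind(records$centroid_x_um, records$centroid_y_um)
  bundle <- if (!is.null(records$bundle_id)) records$bundle_id
  else if (n == 1) 1L
  else cutree(hclust(dist(cent), method = "single"), h = bundle_gap_um)
  ub <- unique(bundle)
  bc <- do.call(rbind, lapply(ub, function(b)
    colMeans(cent[bundle == b, , drop = FALSE])))
  rownames(bc) <- as.character(ub)
  # pith location: the section centre when known; otherwise the unweighted
  # mean of cluster centroids (weighting by vessel count would drag the
  # estimate toward vessel-rich bundles and distort every pith distance)
  pith <- pith_center %||% attr(records, "pith_center_um") %||% colMeans(bc)

  axis_pos <- numeric(n)
  if (length(ub) > 1) {
    # ring layout: the inner->outer coordinate is the pith distance itself
    # (immune to per-bundle axis tilt)
    axis_pos <- sqrt((cent[, 1] - pith[1])^2 + (cent[, 2] - pith[2])^2)
  } else {
    # isolated bundle: first principal direction of the centroids, oriented
    # so diameters increase outward (MX is wider)
    cc <- sweep(cent, 2, colMeans(cent))
    u <- if (n >= 2) svd(cc, nu = 0, nv = 1)$v[, 1] else c(1, 0)
    dcor <- suppressWarnings(cor(as.numeric(cc %*% u), records$diameter_um))
    if (!is.na(dcor) && dcor < 0) u <- -u
    axis_pos <- as.numeric(cc %*% u)
  }

  # A split is trusted when the cluster is large enough and the clearance at
  # the split clearly exceeds within-group clearances, or is moderate while
  # the inner group is distinctly narrower (the PX/MX diameter contrast).
  cluster_split <- function(m) {
    sp <- split_bundle_types(axis_pos[m], records$diameter_um[m],
                             px_diameter_cutoff)
    sp$trusted <- FALSE
    if (length(m) >= 2 && is.finite(sp$boundary) && is.finite(sp$gap)) {
      dr <- mean(records$diameter_um[m][sp$type == "PX"]) /
        mean(records$diameter_um[m][sp$type == "MX"])
      # the diameter-contrast branch needs both groups to be real groups: a
      # single outlying vessel at a chain tip must not certify a split
      sp$trusted <-
        (length(m) >= 5 &&
           (sp$gap >= 8 ||
              (sp$gap >= 5 && dr <= 0.75 && min(table(sp$type)) >= 2))) ||
        # small clusters (sparse bundles) self-split only on decisive
        # evidence: a wide clearance plus the PX/MX diameter contrast
        (sp$gap >= 8 && dr <= 0.75)
    }
    sp
  }

  # Detached fragments (an interrupted metaxylem file, a protoxylem cluster
  # whose file broke off) yield untrustworthy splits. Reunite each with a
  # nearby cluster, but only when the union's split becomes trustworthy -
  # this reattaches a fragment to its parent bundle while refusing merges
  # into the wrong bundle (those collapse the union's PX-MX clearance).
  for (iter in seq_len(length(ub) + 1L)) {
    ub <- unique(bundle)
    if (length(ub) < 2) break
    trust <- vapply(ub, function(b) cluster_split(which(bundle == b))$trusted,
                    logical(1))
    bad <- ub[!trust]
    if (!length(bad)) break
    sizes <- vapply(bad, function(b) sum(bundle == b), numeric(1))
    merged <- FALSE
    for (b in bad[order(sizes)]) {
      m <- which(bundle == b)
      others <- setdiff(ub, b)
      dmin <- vapply(others, function(o) {
        mo <- which(bundle == o)
        sqrt(min(outer(cent[m, 1], cent[mo, 1], "-")^2 +
                   outer(cent[m, 2], cent[mo, 2], "-")^2))
      }, numeric(1))
      for (o in others[order(dmin)][dmin[order(dmin)] <= 60]) {
        if (cluster_split(c(m, which(bundle == o)))$trusted) {
          bundle[m] <- o
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }

  ub <- unique(bundle)
  type <- rep(NA_character_, n)
  boundaries <- rep(NA_real_, length(ub))
  names(boundaries) <- as.character(ub)
  for (b in ub) {
    m <- which(bundle == b)
    sp <- cluster_split(m)
    if (sp$trusted) {
      type[m] <- sp$type
      boundaries[as.character(b)] <- sp$boundary
    }
  }

  trusted <- names(boundaries)[is.finite(boundaries)]
  todo_b <- setdiff(as.character(ub), trusted)
  if (length(trusted)) {
    bc2 <- do.call(rbind, lapply(ub, function(b)
      colMeans(cent[bundle == b, , drop = FALSE])))
    rownames(bc2) <- as.character(ub)
    for (b in todo_b) {
      # nearest trusted cluster as the reference boundary
      d2 <- rowSums(sweep(bc2[trusted, , drop = FALSE], 2, bc2[b, ])^2)
      bnd <- boundaries[trusted[which.min(d2)]]
      m <- which(as.character(bundle) == b)
      type[m] <- ifelse(axis_pos[m] < bnd, "PX", "MX")
    }
  } else {
    for (b in todo_b) {
      m <- which(as.character(bundle) == b)
      sp <- split_bundle_types(axis_pos[m], records$diameter_um[m],
                               px_diameter_cutoff)
      ty <- sp$type
      ty[is.na(ty)] <- ifelse(records$diameter_um[m][is.na(ty)] <
                                px_diameter_cutoff, "PX", "MX")
      type[m] <- ty
    }
  }
  type
}

#' Apply all classification steps to a measured vessel table
#'
#' Populates `expanding`, `conductive_bf`, `conductive_ef` and `type` from
#' the measured fields only, so the operation is idempotent: re-classifying
#' an already classified table leaves it unchanged.
#'
#' @param records output of [measure_vessels()] (or a truth-derived table).
#' @param theta_bf bright-field wall-completeness threshold (default 0.9).
#' @param expanding_quantile percentile for [flag_expanding()] (default 50).
#' @param bundle_gap_um,px_diameter_cutoff,pith_center see
#'   [assign_xylem_type()].
#' @return `records` with the four call columns added/overwritten.
#' @export
classify_all <- function(records, theta_bf = 0.9, expanding_quantile = 50,
                         bundle_gap_um = 34, px_diameter_cutoff = 8,
                         pith_center = NULL) {
  records$expanding <- flag_expanding(records, theta_bf, expanding_quantile)
  records$conductive_bf <- classify_bf(records$wall_completeness,
                                       records$expanding, theta_bf)
  records$conductive_ef <- classify_ef(records$stain_fraction)
  records$type <- assign_xylem_type(records, bundle_gap_um,
                                    px_diameter_cutoff, pith_center)
  records
}
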