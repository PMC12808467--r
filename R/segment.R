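# Seed segmentation: one label per seed from the initial foreground mask.
#
# Stage order (see segment_lot): watershed refinement on the Euclidean
# distance transform, repair of jagged edges, convex-defect splitting of
# still-touching seeds anchored on Harris corner responses, and merge of
# over-segmented fragments. Every stage preserves the labeled-mask invariants
# (contiguous labels, one 8-connected component per label).

#' Segmentation parameters
#'
#' @param peak_min_distance_px minimum separation of watershed markers (px);
#'   adjacent regions with closer distance-map peaks are merged.
#' @param peak_footprint_px window side for distance-map local maxima.
#' @param watershed_tolerance minimum distance-map depth separating two
#'   markers (h-maxima suppression of shallow maxima).
#' @param min_seed_area_px components smaller than this are discarded and
#'   splits creating smaller parts are rejected.
#' @param defect_depth_min_px minimum convexity-defect depth to consider a
#'   split.
#' @param harris_k Harris & Stephens sensitivity.
#' @param harris_window_px Gaussian window side for the Harris structure
#'   tensor.
#' @param corner_search_radius_px search radius around a defect's deepest
#'   point for the corner anchor.
#' @param split_max_gap_px maximum length of a cut line between two defects.
#' @param merge_area_frac fragments below this fraction of the lot-median area
#'   are merge candidates.
#' @param merge_length_frac fragments below this fraction of the lot-median
#'   length are merge candidates.
#' @param touch_solidity_max objects with solidity below this AND area above
#'   `touch_area_factor` x lot-median area are treated as touching clumps.
#' @param touch_area_factor see `touch_solidity_max`. Pairs of below-median
#'   seeds merge to about 1.5x the lot median, so the gate sits below that.
#' @param single_defect_cut when a touching clump exposes only one qualifying
#'   defect (deeply overlapping pairs develop a single pronounced notch), cut
#'   from its anchor to the nearest opposite boundary point instead of
#'   leaving the clump unsplit.
#' @param boundary_refine_iters iterations of the ellipse-model boundary
#'   refinement between touching seeds (0 disables): each seed's free contour
#'   (away from the contact) is fitted with a direct least-squares ellipse and
#'   contested pixels are reassigned to the seed with the smaller normalized
#'   elliptical radius.
#' @export
segmentation_params <- function(peak_min_distance_px = 15,
                                peak_footprint_px = 11L,
                                watershed_tolerance = 1,
                                min_seed_area_px = 200L,
                                defect_depth_min_px = 4,
                                harris_k = 0.04,
                                harris_window_px = 5L,
                                corner_search_radius_px = 10,
                                split_max_gap_px = 60,
                                merge_area_frac = 0.55,
                                merge_length_frac = 0.6,
                                touch_solidity_max = 0.92,
                                touch_area_factor = 1.35,
                                single_defect_cut = TRUE,
                                boundary_refine_iters = 2L) {
  stopifnot(peak_min_distance_px > 0, peak_footprint_px > 0,
            min_seed_area_px > 0, defect_depth_min_px > 0,
            corner_search_radius_px > 0, split_max_gap_px > 0,
            merge_area_frac > 0, merge_area_frac < 1,
            merge_length_frac > 0, merge_length_frac < 1)
  structure(as.list(environment()), class = "segmentation_params")
}

# Ordered outer contour (1-based row/col) of a binary crop's single object.
object_contour <- function(bin) {
  oc <- EBImage::ocontour(matrix(as.numeric(bin != 0), nrow(bin), ncol(bin)))
  if (length(oc) == 0L) return(NULL)
  # keep the longest contour if spurious extras appear
  oc <- oc[[which.max(vapply(oc, nrow, 1L))]]
  cbind(oc[, 1] + 1L, oc[, 2] + 1L)
}

# Second-moment ellipse axis lengths (major, minor) of pixel coordinates.
moment_axes <- function(pts) {
  n <- nrow(pts)
  if (n < 2L) return(c(0, 0))
  cv <- stats::cov(pts) * (n - 1) / n
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  c(4 * sqrt(ev[1]), 4 * sqrt(ev[2]))
}

# Solidity (area / filled convex hull area) of a binary crop.
crop_solidity <- function(bin) {
  a <- sum(bin != 0)
  if (a == 0L) return(NA_real_)
  a / sum(fill_convex_hull(bin))
}

# Keep only each label's largest 8-connected component (invariant repair).
enforce_single_component <- function(lab) {
  if (max(lab) == 0L) return(lab)
  for (k in seq_len(max(lab))) {
    ind <- which(lab == k)
    if (length(ind) == 0L) next
    bb <- bbox_of(ind, dim(lab), pad = 1L)
    crop <- lab[bb$r1:bb$r2, bb$c1:bb$c2]
    cl <- label8(crop == k)
    if (max(cl) > 1L) {
      keep <- which.max(tabulate(cl[cl > 0L]))
      crop[crop == k & cl != keep] <- 0L
      lab[bb$r1:bb$r2, bb$c1:bb$c2] <- crop
    }
  }
  lab
}

#' Watershed refinement of the initial seed mask
#'
#' Computes the Euclidean distance transform of the foreground and floods it
#' with the watershed transform: local maxima of the distance map act as
#' markers, with maxima detected within a `peak_footprint_px` window
#' (`ext = (footprint - 1) / 2`) and shallow maxima suppressed by
#' `watershed_tolerance`. Adjacent regions whose distance-map peaks are closer
#' than `peak_min_distance_px` are merged (minimum marker separation), and
#' components smaller than `min_seed_area_px` are removed.
#'
#' @param foreground binary matrix from [remove_background()].
#' @param params a [segmentation_params()].
#' @return a [labeled_mask()]; empty foreground yields `n_seeds = 0`.
#' @export
watershed_refine <- function(foreground, params = segmentation_params()) {
  fg <- matrix(as.numeric(foreground != 0), nrow(foreground), ncol(foreground))
  if (!any(fg > 0)) return(labeled_mask(matrix(0L, nrow(fg), ncol(fg))))
  dm <- EBImage::distmap(fg)
  fp <- as.integer(params$peak_footprint_px)
  if (fp %% 2L == 0L) fp <- fp + 1L
  ws <- EBImage::watershed(dm, tolerance = params$watershed_tolerance,
                           ext = max((fp - 1L) %/% 2L, 1L))
  lab <- relabel_raster_order(matrix(as.integer(ws), nrow(fg), ncol(fg)))
  n <- max(lab)
  if (n > 1L) {
    # merge adjacent regions whose peaks violate the minimum marker separation
    idx <- which(lab > 0L)
    grp <- lab[idx]
    peak_of <- vapply(split(idx, grp), function(ii) ii[which.max(dm[ii])], 0L)
    pr <- ((peak_of - 1L) %% nrow(fg)) + 1L
    pc <- ((peak_of - 1L) %/% nrow(fg)) + 1L
    adj <- label_adjacency(lab)
    if (!is.null(adj)) {
      d <- sqrt((pr[adj$a] - pr[adj$b])^2 + (pc[adj$a] - pc[adj$b])^2)
      close <- adj[d < params$peak_min_distance_px, , drop = FALSE]
      if (nrow(close) > 0L) {
        g <- igraph::graph_from_edgelist(
          matrix(as.character(c(close$a, close$b)), ncol = 2), directed = FALSE)
        memb <- igraph::components(g)$membership
        map <- seq_len(n)
        for (v in names(memb)) map[as.integer(v)] <- n + memb[[v]]
        lab[lab > 0L] <- map[lab[lab > 0L]]
        lab <- relabel_raster_order(lab)
      }
    }
  }
  lab <- enforce_single_component(lab)
  lab <- drop_small(lab, params$min_seed_area_px)
  labeled_mask(lab)
}

#' Repair jagged object edges
#'
#' For each object, the boundary-irregularity residue (the object XOR its
#' morphological closing) is skeletonized; straight chords are drawn between
#' skeleton endpoints of the same residue region and enclosed slivers are
#' filled into the object. Repairs changing an object's area by more than 5%
#' are reverted, residues smaller than `min_residue_px` are ignored, and
#' repaired pixels never overwrite other labels.
#'
#' @param mask a [labeled_mask()].
#' @param brush_px closing structuring-element diameter.
#' @param min_residue_px residue components smaller than this are ignored.
#' @param max_area_change maximum tolerated relative area increase.
#' @return a [labeled_mask()] with the same number of objects.
#' @export
smooth_edges <- function(mask, brush_px = 5L, min_residue_px = 5L,
                         max_area_change = 0.05) {
  stopifnot(inherits(mask, "labeled_mask"))
  lab <- mask$labels
  if (mask$n_seeds == 0L) return(mask)
  brush <- EBImage::makeBrush(brush_px, "disc")
  for (k in seq_len(mask$n_seeds)) {
    ind <- which(lab == k)
    bb <- bbox_of(ind, dim(lab), pad = brush_px)
    sub <- lab[bb$r1:bb$r2, bb$c1:bb$c2]
    obj <- matrix(as.numeric(sub == k), nrow(sub), ncol(sub))
    closed <- EBImage::closing(obj, brush)
    residue <- matrix(as.integer(closed > 0 & obj == 0), nrow(obj), ncol(obj))
    rlab <- drop_small(label8(residue), min_residue_px)
    if (max(rlab) == 0L) next
    skel <- thin_zs(rlab > 0L)
    ends <- skel == 1L & neighbor_count8(skel) == 1L
    cand <- obj
    for (rc in seq_len(max(rlab))) {
      ep <- which(ends & rlab == rc, arr.ind = TRUE)
      if (nrow(ep) < 2L) next
      # connect endpoint pairs, nearest first
      while (nrow(ep) >= 2L) {
        d2 <- as.matrix(dist(ep))^2; diag(d2) <- Inf
        ij <- arrayInd(which.min(d2), dim(d2))
        cand[line_pixels(ep[ij[1], ], ep[ij[2], ])] <- 1
        ep <- ep[-ij, , drop = FALSE]
      }
    }
    filled <- EBImage::fillHull(cand)
    a0 <- sum(obj); a1 <- sum(filled > 0)
    if (a1 - a0 > max_area_change * a0) next
    newpx <- filled > 0 & sub == 0L  # never bleed into other labels
    sub[newpx] <- k
    lab[bb$r1:bb$r2, bb$c1:bb$c2] <- sub
  }
  lab <- enforce_single_component(lab)
  labeled_mask(relabel_raster_order(lab))
}

# Convexity defects of the single object in a binary crop.
# Returns a list of (depth, deepest point row/col) for defects deeper than min_depth.
convexity_defects <- function(bin, min_depth) {
  P <- object_contour(bin)
  if (is.null(P) || nrow(P) < 8L) return(list())
  H <- sort(grDevices::chull(P))
  n <- nrow(P)
  out <- list()
  for (i in seq_along(H)) {
    a <- H[i]; b <- if (i < length(H)) H[i + 1L] else H[1L] + n
    arc <- if (b - a > 1L) ((a:(b - 1L))[-1L] - 1L) %% n + 1L else integer(0)
    if (length(arc) == 0L) next
    pa <- P[a, ]; pb <- P[(b - 1L) %% n + 1L, ]
    v <- pb - pa
    len <- sqrt(sum(v^2))
    if (len < 1e-9) next
    d <- abs((P[arc, 1] - pa[1]) * v[2] - (P[arc, 2] - pa[2]) * v[1]) / len
    j <- which.max(d)
    if (d[j] >= min_depth)
      out[[length(out) + 1L]] <- list(depth = d[j], point = P[arc[j], ],
                                      arc = arc)
  }
  out
}

# Harris & Stephens corner response of the contour curve of a binary crop.
harris_response <- function(bin, window_px, k) {
  P <- object_contour(bin)
  cimg <- matrix(0, nrow(bin), ncol(bin))
  cimg[P] <- 1
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  ix <- EBImage::filter2(cimg, sx)
  iy <- EBImage::filter2(cimg, t(sx))
  w <- as.integer(window_px); if (w %% 2L == 0L) w <- w + 1L
  g <- EBImage::makeBrush(w, "gaussian", sigma = max(w / 3, 1))
  sxx <- EBImage::filter2(ix * ix, g)
  syy <- EBImage::filter2(iy * iy, g)
  sxy <- EBImage::filter2(ix * iy, g)
  r <- (sxx * syy - sxy^2) - k * (sxx + syy)^2
  list(response = r, contour = P)
}

#' Split still-touching seeds along convexity defects
#'
#' Objects flagged as touching clumps (solidity below `touch_solidity_max` and
#' area above `touch_area_factor` x lot-median) are examined for convexity
#' defects deeper than `defect_depth_min_px`. Within each defect, the
#' inflexion point is the contour pixel of maximal Harris corner response
#' within `corner_search_radius_px` of the defect's deepest point. Defect
#' anchors are paired mutually-nearest across distinct defects (greedy,
#' shortest gap first, gap at most `split_max_gap_px`) and the object is cut
#' along the connecting straight line. Cuts creating parts smaller than
#' `min_seed_area_px` are rejected. Finally, boundaries between touching
#' seeds - whether created here or by the watershed - are refined against
#' direct least-squares ellipse fits of each seed's free contour
#' (`boundary_refine_iters`), which also restores cut-line pixels to the
#' nearer seed.
#'
#' @param mask a [labeled_mask()] (post-watershed).
#' @param params a [segmentation_params()].
#' @return a [labeled_mask()].
#' @export
split_touching <- function(mask, params = segmentation_params()) {
  stopifnot(inherits(mask, "labeled_mask"))
  lab <- mask$labels
  if (mask$n_seeds < 1L) return(mask)
  areas <- tabulate(lab[lab > 0L], mask$n_seeds)
  med <- median(areas)
  next_label <- mask$n_seeds
  for (k in seq_len(mask$n_seeds)) {
    if (areas[k] <= params$touch_area_factor * med) next
    ind <- which(lab == k)
    bb <- bbox_of(ind, dim(lab), pad = 8L)
    sub <- lab[bb$r1:bb$r2, bb$c1:bb$c2]
    obj <- matrix(as.integer(sub == k), nrow(sub), ncol(sub))
    sol <- crop_solidity(obj)
    if (is.na(sol) || sol >= params$touch_solidity_max) next
    defects <- convexity_defects(obj, params$defect_depth_min_px)
    if (length(defects) < 1L ||
        (length(defects) == 1L && !isTRUE(params$single_defect_cut))) next
    hr <- harris_response(obj, params$harris_window_px, params$harris_k)
    anchors <- t(vapply(defects, function(df) {
      P <- hr$contour
      d2 <- (P[, 1] - df$point[1])^2 + (P[, 2] - df$point[2])^2
      near <- which(d2 <= params$corner_search_radius_px^2)
      if (length(near) == 0L) return(as.numeric(df$point))
      as.numeric(P[near[which.max(hr$response[P[near, , drop = FALSE]])], ])
    }, numeric(2)))
    # try one cut; returns the cut object or NULL when parts would be too small
    try_cut <- function(cur, p1, p2) {
      cut <- line_pixels(p1, p2)
      trial <- cur
      trial[cut] <- 0L
      cl <- label8(trial)
      if (max(cl) < 2L) {
        # a 1-px diagonal line may not break 8-connectivity; thicken the cut
        cut2 <- rbind(cut, cbind(cut[, 1] + 1L, cut[, 2]),
                      cbind(cut[, 1], cut[, 2] + 1L))
        cut2 <- cut2[cut2[, 1] <= nrow(cur) & cut2[, 2] <= ncol(cur), ]
        trial <- cur
        trial[cut2] <- 0L
        cl <- label8(trial)
        if (max(cl) < 2L) return(NULL)
      }
      if (min(tabulate(cl[cl > 0L])) < params$min_seed_area_px) return(NULL)
      trial
    }
    cur <- obj
    if (nrow(anchors) >= 2L) {
      # pair anchors across distinct defects, shortest gap first
      nd <- nrow(anchors)
      gaps <- expand.grid(i = seq_len(nd), j = seq_len(nd))
      gaps <- gaps[gaps$i < gaps$j, ]
      gaps$d <- sqrt((anchors[gaps$i, 1] - anchors[gaps$j, 1])^2 +
                       (anchors[gaps$i, 2] - anchors[gaps$j, 2])^2)
      gaps <- gaps[gaps$d <= params$split_max_gap_px, ]
      gaps <- gaps[order(gaps$d), ]
      used <- logical(nd)
      for (g in seq_len(nrow(gaps))) {
        i <- gaps$i[g]; j <- gaps$j[g]
        if (used[i] || used[j]) next
        trial <- try_cut(cur, anchors[i, ], anchors[j, ])
        if (is.null(trial)) next
        cur <- trial
        used[i] <- used[j] <- TRUE
      }
    } else if (isTRUE(params$single_defect_cut)) {
      # single deep defect: cut across the neck to the nearest opposite
      # boundary point (contour-index distance at least 20% of the contour)
      P <- hr$contour
      np <- nrow(P)
      d2a <- (P[, 1] - anchors[1, 1])^2 + (P[, 2] - anchors[1, 2])^2
      ia <- which.min(d2a)
      circ <- pmin(abs(seq_len(np) - ia), np - abs(seq_len(np) - ia))
      cand <- which(circ >= 0.2 * np)
      cand <- cand[order(d2a[cand])]
      for (t in head(cand, 8L)) {
        if (sqrt(d2a[t]) > params$split_max_gap_px) break
        trial <- try_cut(cur, anchors[1, ], P[t, ])
        if (!is.null(trial)) { cur <- trial; break }
      }
    }
    parts <- label8(cur)
    np <- max(parts)
    if (np <= 1L) next
    # largest part keeps label k; the others get fresh labels
    ord <- order(-tabulate(parts[parts > 0L]))
    sub[sub == k] <- 0L
    sub[parts == ord[1L]] <- k
    for (p in ord[-1L]) {
      next_label <- next_label + 1L
      sub[parts == p] <- next_label
    }
    lab[bb$r1:bb$r2, bb$c1:bb$c2] <- sub
  }
  lab <- refine_pair_boundaries(lab, params)
  labeled_mask(relabel_raster_order(lab))
}

# Ellipse-model refinement of the boundary between touching seeds.
#
# Seed pairs in contact - directly adjacent labels, or labels separated by the
# 1-px background gap a cut line leaves - are re-partitioned: each seed's free
# contour (pixels away from the contact zone) is fitted with a direct
# least-squares ellipse, and every pixel of the pair (plus the gap pixels) is
# assigned to the seed whose fitted ellipse it is relatively closest to
# (smaller normalized elliptical radius). Reassignments that would break a
# seed's connectivity or shrink it below min_seed_area_px are discarded.
refine_pair_boundaries <- function(lab, params) {
  iters <- params$boundary_refine_iters
  if (is.null(iters) || iters < 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  for (it in seq_len(iters)) {
    # contact pairs: shared boundaries ...
    adj <- label_adjacency(lab)
    pair_list <- if (!is.null(adj)) adj[adj$n >= 4L, c("a", "b"), drop = FALSE]
    else data.frame(a = integer(0), b = integer(0))
    # ... plus background pixels bridging two labels (cut-line gaps)
    nbmin <- matrix(Inf, nr, nc); nbmax <- matrix(0L, nr, nc)
    pad <- matrix(0L, nr + 2L, nc + 2L)
    pad[2:(nr + 1L), 2:(nc + 1L)] <- lab
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      s <- pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
      pos <- s > 0L
      nbmin[pos] <- pmin(nbmin[pos], s[pos])
      nbmax[pos] <- pmax(nbmax[pos], s[pos])
    }
    gapsel <- lab == 0L & is.finite(nbmin) & nbmax > nbmin
    if (any(gapsel)) {
      gp <- unique(data.frame(a = nbmin[gapsel], b = nbmax[gapsel]))
      pair_list <- unique(rbind(pair_list, gp))
    }
    if (nrow(pair_list) == 0L) break
    for (r in seq_len(nrow(pair_list))) {
      a <- pair_list$a[r]; b <- pair_list$b[r]
      gpx <- which(gapsel & nbmin == a & nbmax == b)
      ind <- c(which(lab == a | lab == b), gpx)
      if (length(ind) == 0L) next
      bb <- bbox_of(ind, dim(lab), pad = 4L)
      sub <- lab[bb$r1:bb$r2, bb$c1:bb$c2]
      gsub <- matrix(FALSE, nrow(sub), ncol(sub))
      if (length(gpx)) {
        grr <- ((gpx - 1L) %% nr) + 1L - bb$r1 + 1L
        gcc <- ((gpx - 1L) %/% nr) + 1L - bb$c1 + 1L
        gsub[cbind(grr, gcc)] <- TRUE
      }
      pa <- which(sub == a, arr.ind = TRUE)
      pb <- which(sub == b, arr.ind = TRUE)
      if (nrow(pa) < 30L || nrow(pb) < 30L) next
      fit_of <- function(own, other) {
        P <- object_contour(own)
        if (is.null(P)) return(NULL)
        contact <- matrix(as.numeric(!(other | gsub)), nrow(sub), ncol(sub))
        dcon <- EBImage::distmap(contact)
        arc <- P[dcon[P] > 3, , drop = FALSE]
        f <- if (nrow(arc) >= 15L) fit_ellipse_conic(arc) else NULL
        if (is.null(f)) {
          # moment fallback: boundary at Mahalanobis radius 2
          pts <- which(own, arr.ind = TRUE)
          cv <- stats::cov(pts) * (nrow(pts) - 1) / nrow(pts)
          si <- tryCatch(solve(cv), error = function(e) NULL)
          if (is.null(si)) return(NULL)
          f <- list(center = colMeans(pts), Qn = si / 4)
        }
        f
      }
      fa <- fit_of(sub == a, sub == b)
      fb <- fit_of(sub == b, sub == a)
      if (is.null(fa) || is.null(fb)) next
      q <- rbind(pa, pb, which(gsub, arr.ind = TRUE))
      newlab <- ifelse(conic_radius(fa, q) <= conic_radius(fb, q), a, b)
      if (min(tabulate(factor(newlab, levels = c(a, b)))) <
          params$min_seed_area_px) next
      sub2 <- sub
      sub2[q] <- newlab
      if (max(label8(sub2 == a)) != 1L || max(label8(sub2 == b)) != 1L) next
      lab[bb$r1:bb$r2, bb$c1:bb$c2] <- sub2
    }
  }
  lab
}

# Shared-boundary pixel-pair counts between adjacent labels (8-connectivity).
label_adjacency <- function(lab) {
  pairs <- NULL
  nr <- nrow(lab); nc <- ncol(lab)
  for (s in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    dr <- s[1]; dc <- s[2]
    rs <- seq_len(nr - dr)
    cs <- if (dc >= 0) seq_len(nc - dc) else seq(1 - dc, nc)
    a <- lab[rs, cs, drop = FALSE]
    b <- lab[rs + dr, cs + dc, drop = FALSE]
    sel <- a > 0L & b > 0L & a != b
    if (any(sel))
      pairs <- rbind(pairs, cbind(pmin(a[sel], b[sel]), pmax(a[sel], b[sel])))
  }
  if (is.null(pairs)) return(NULL)
  stats::aggregate(list(n = rep(1L, nrow(pairs))),
                   by = list(a = pairs[, 1], b = pairs[, 2]), FUN = sum)
}

#' Merge over-segmented fragments
#'
#' A fragment is merge-eligible when its area is below
#' `merge_area_frac` x lot-median area or its length below
#' `merge_length_frac` x lot-median length. Eligible fragments merge into the
#' neighbour with the longest shared boundary, accepted only when the merged
#' object's solidity is at least the area-weighted mean solidity of the parts
#' minus 0.02 (convex-defect plausibility). Iterates to a fixpoint (at most 10
#' rounds); isolated fragments without neighbours are kept.
#'
#' @param mask a [labeled_mask()].
#' @param params a [segmentation_params()].
#' @return a [labeled_mask()]; total foreground pixels are unchanged.
#' @export
merge_oversegmented <- function(mask, params = segmentation_params()) {
  stopifnot(inherits(mask, "labeled_mask"))
  lab <- mask$labels
  if (mask$n_seeds < 2L) return(mask)
  crop_of <- function(k) {
    ind <- which(lab == k)
    bb <- bbox_of(ind, dim(lab), pad = 1L)
    list(bb = bb, bin = lab[bb$r1:bb$r2, bb$c1:bb$c2] == k)
  }
  for (round in 1:10) {
    n <- max(lab)
    if (n < 2L) break
    areas <- tabulate(lab[lab > 0L], n)
    live <- which(areas > 0L)
    lens <- vapply(live, function(k)
      moment_axes(which(lab == k, arr.ind = TRUE))[1], 0)
    med_area <- median(areas[live])
    med_len <- median(lens)
    eligible <- live[areas[live] < params$merge_area_frac * med_area |
                       lens < params$merge_length_frac * med_len]
    if (length(eligible) == 0L) break
    adj <- label_adjacency(lab)
    if (is.null(adj)) break
    changed <- FALSE
    touched <- logical(n)
    for (k in eligible[order(areas[eligible])]) {
      if (touched[k]) next
      nb <- rbind(adj[adj$a == k, c("b", "n")],
                  setNames(adj[adj$b == k, c("a", "n")], c("b", "n")))
      nb <- nb[!touched[nb$b], , drop = FALSE]
      if (nrow(nb) == 0L) next
      tgt <- nb$b[which.max(nb$n)]
      # convex-defect plausibility of the merged object
      ind <- which(lab == k | lab == tgt)
      bb <- bbox_of(ind, dim(lab), pad = 1L)
      sub <- lab[bb$r1:bb$r2, bb$c1:bb$c2]
      sol_k <- crop_solidity(sub == k)
      sol_t <- crop_solidity(sub == tgt)
      sol_m <- crop_solidity(sub == k | sub == tgt)
      wmean <- (sol_k * areas[k] + sol_t * areas[tgt]) / (areas[k] + areas[tgt])
      if (is.na(sol_m) || sol_m < wmean - 0.02) next
      lab[lab == k] <- tgt
      touched[k] <- touched[tgt] <- TRUE
      changed <- TRUE
    }
    if (!changed) break
    lab <- relabel_raster_order(lab)
  }
  labeled_mask(relabel_raster_order(lab))
}

#' Full seed-lot segmentation
#'
#' Orchestrates [remove_background()], [watershed_refine()], [smooth_edges()],
#' [split_touching()] and [merge_oversegmented()]; deterministic given inputs
#' and parameters. Object counts are logged after every stage.
#'
#' @param stack an [msi_stack()].
#' @param rgb optional [rgb_image()] companion; when supplied, overexposed
#'   pixels are detected and returned as a validity mask in the
#'   `valid_pixels` attribute of the result (for [measure_spectral()]).
#' @param params a [segmentation_params()].
#' @param bg_params a [background_params()].
#' @param oe_params an [overexposure_params()].
#' @param verbose log per-stage object counts.
#' @param log_file optional log file path.
#' @return a [labeled_mask()].
#' @export
segment_lot <- function(stack, rgb = NULL, params = segmentation_params(),
                        bg_params = background_params(),
                        oe_params = overexposure_params(),
                        verbose = TRUE, log_file = NULL) {
  say <- function(stage, msg) if (verbose) log_msg(stage, msg, file = log_file)
  fg <- remove_background(stack, bg_params)
  say("remove_background", sprintf("foreground px: %d", sum(fg)))
  m <- watershed_refine(fg, params)
  say("watershed_refine", sprintf("objects: %d", m$n_seeds))
  m <- smooth_edges(m)
  say("smooth_edges", sprintf("objects: %d", m$n_seeds))
  m <- split_touching(m, params)
  say("split_touching", sprintf("objects: %d", m$n_seeds))
  m <- merge_oversegmented(m, params)
  say("merge_oversegmented", sprintf("objects: %d", m$n_seeds))
  if (!is.null(rgb)) {
    oe <- detect_overexposed(rgb, oe_params)
    attr(m, "valid_pixels") <- matrix(as.integer(oe == 0L), nrow(oe), ncol(oe))
    say("detect_overexposed", sprintf("flagged px: %d", sum(oe)))
  }
  m
}
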