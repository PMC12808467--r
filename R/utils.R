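# Internal raster helpers shared by the pipeline stages.
# Convention: image matrices are height x width (row, col); masks are integer
# matrices with background 0; all object connectivity is 8-connected.

#' 8-connected component labeling
#'
#' Labels foreground pixels of a binary matrix into 8-connected components,
#' numbered 1..n in raster-scan order of their first pixel.
#'
#' @param mask binary matrix (0 background, non-zero foreground).
#' @return integer matrix of labels.
#' @keywords internal
label8 <- function(mask) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  l4 <- EBImage::bwlabel(m)
  storage.mode(l4) <- "integer"
  k <- max(l4)
  if (k <= 1L) return(l4)
  # merge 4-connected labels that touch diagonally
  a1 <- l4[-nrow(l4), -ncol(l4)]; b1 <- l4[-1, -1]
  a2 <- l4[-nrow(l4), -1]; b2 <- l4[-1, -ncol(l4)]
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  edges <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  if (nrow(edges) == 0L) return(relabel_raster_order(l4))
  g <- igraph::graph_from_edgelist(matrix(as.character(edges), ncol = 2), directed = FALSE)
  g <- igraph::add_vertices(g, sum(!(as.character(seq_len(k)) %in% igraph::V(g)$name)),
                            name = setdiff(as.character(seq_len(k)), igraph::V(g)$name))
  comp <- igraph::components(g)$membership
  map <- integer(k)
  map[as.integer(names(comp))] <- as.integer(comp)
  out <- l4
  out[out > 0L] <- map[out[out > 0L]]
  relabel_raster_order(out)
}

# Renumber positive labels 1..n in raster-scan order of first occurrence.
relabel_raster_order <- function(lab) {
  pos <- which(lab > 0L)
  if (length(pos) == 0L) {
    storage.mode(lab) <- "integer"
    return(lab)
  }
  first <- pos[!duplicated(lab[pos])]
  old <- lab[first]
  map <- integer(max(old))
  map[old] <- seq_along(old)
  lab[pos] <- map[lab[pos]]
  storage.mode(lab) <- "integer"
  lab
}

# Drop components smaller than min_px from an integer label matrix (relabels).
drop_small <- function(lab, min_px) {
  if (max(lab) == 0L) return(lab)
  sizes <- tabulate(lab[lab > 0L])
  kill <- which(sizes < min_px)
  if (length(kill)) lab[lab %in% kill] <- 0L
  relabel_raster_order(lab)
}

#' Exact local box mean with edge correction
#'
#' Mean of each pixel's (w x w) neighbourhood, computed with integral images;
#' windows are clipped at the image border (no padding bias).
#'
#' @param img numeric matrix.
#' @param w odd window side in pixels.
#' @return matrix of local means, same shape.
#' @keywords internal
box_mean <- function(img, w) {
  stopifnot(w >= 1, w %% 2 == 1)
  h <- nrow(img); wd <- ncol(img)
  r <- (w - 1L) / 2L
  S <- matrix(0, h + 1L, wd + 1L)
  S[-1L, -1L] <- apply(apply(img, 2L, cumsum), 1L, cumsum) |> t()
  r1 <- pmax(seq_len(h) - r, 1L); r2 <- pmin(seq_len(h) + r, h)
  c1 <- pmax(seq_len(wd) - r, 1L); c2 <- pmin(seq_len(wd) + r, wd)
  tot <- S[r2 + 1L, c2 + 1L, drop = FALSE] - S[r1, c2 + 1L, drop = FALSE] -
    S[r2 + 1L, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
  cnt <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  tot / cnt
}

# Pixels of the straight segment between p1 and p2 (row, col), inclusive.
line_pixels <- function(p1, p2) {
  n <- max(abs(p2 - p1)) + 1L
  cbind(round(seq(p1[1], p2[1], length.out = n)),
        round(seq(p1[2], p2[2], length.out = n)))
}

# Bounding box (+pad, clipped) of positive pixels; NULL when empty.
bbox_of <- function(ind, dims, pad = 2L) {
  if (length(ind) == 0L) return(NULL)
  rr <- ((ind - 1L) %% dims[1]) + 1L
  cc <- ((ind - 1L) %/% dims[1]) + 1L
  list(r1 = max(1L, min(rr) - pad), r2 = min(dims[1], max(rr) + pad),
       c1 = max(1L, min(cc) - pad), c2 = min(dims[2], max(cc) + pad))
}

# Filled convex hull (binary matrix) of the foreground pixels of a crop.
fill_convex_hull <- function(bin) {
  pts <- which(bin != 0, arr.ind = TRUE)
  if (nrow(pts) == 0L) return(matrix(0L, nrow(bin), ncol(bin)))
  if (nrow(pts) <= 2L) { out <- matrix(0L, nrow(bin), ncol(bin)); out[pts] <- 1L; return(out) }
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hx <- pts[h, 1]; hy <- pts[h, 2]
  grid <- expand.grid(r = seq_len(nrow(bin)), c = seq_len(ncol(bin)))
  inside <- pracma::inpolygon(grid$r, grid$c, hx, hy, boundary = TRUE)
  matrix(as.integer(inside), nrow(bin), ncol(bin))
}

# Number of 8-neighbours set for each pixel of a binary matrix.
neighbor_count8 <- function(bin) {
  h <- nrow(bin); w <- ncol(bin)
  p <- matrix(0L, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- as.integer(bin != 0)
  n <- matrix(0L, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    n <- n + p[(2:(h + 1L)) + dr, (2:(w + 1L)) + dc]
  }
  n
}

# Zhang-Suen thinning of a small binary crop; returns the 1-px skeleton.
thin_zs <- function(bin) {
  img <- matrix(as.integer(bin != 0), nrow(bin), ncol(bin))
  h <- nrow(img); w <- ncol(img)
  if (h < 3L || w < 3L) return(img)
  shift <- function(m, dr, dc) {
    p <- matrix(0L, h + 2L, w + 2L)
    p[2:(h + 1L), 2:(w + 1L)] <- m
    p[(2:(h + 1L)) + dr, (2:(w + 1L)) + dc]
  }
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      p2 <- shift(img, -1, 0); p3 <- shift(img, -1, 1); p4 <- shift(img, 0, 1)
      p5 <- shift(img, 1, 1);  p6 <- shift(img, 1, 0);  p7 <- shift(img, 1, -1)
      p8 <- shift(img, 0, -1); p9 <- shift(img, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) + (p4 == 0L & p5 == 1L) +
        (p5 == 0L & p6 == 1L) + (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
        (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      if (phase == 1L) {
        cond <- img == 1L & b >= 2L & b <= 6L & a == 1L &
          (p2 * p4 * p6) == 0L & (p4 * p6 * p8) == 0L
      } else {
        cond <- img == 1L & b >= 2L & b <= 6L & a == 1L &
          (p2 * p4 * p8) == 0L & (p2 * p6 * p8) == 0L
      }
      if (any(cond)) { img[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  img
}

# Direct least-squares (Fitzgibbon) ellipse fit to boundary points.
# Returns list(center, Qn) with (p - center)' Qn (p - center) = 1 on the
# ellipse, or NULL when the fit is degenerate.
fit_ellipse_conic <- function(xy) {
  if (nrow(xy) < 8L) return(NULL)
  x <- xy[, 1]; y <- xy[, 2]
  mx <- mean(x); my <- mean(y); sc <- max(sd(x), sd(y))
  if (!is.finite(sc) || sc < 1e-9) return(NULL)
  xs <- (x - mx) / sc; ys <- (y - my) / sc
  D <- cbind(xs^2, xs * ys, ys^2, xs, ys, 1)
  S <- crossprod(D)
  C <- matrix(0, 6, 6); C[1, 3] <- C[3, 1] <- 2; C[2, 2] <- -1
  M <- tryCatch(solve(S, C), error = function(e) NULL)
  if (is.null(M)) return(NULL)
  ev <- eigen(M)
  vecs <- Re(ev$vectors)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  i <- which(cond > 1e-12 & is.finite(Re(ev$values)))
  if (length(i) == 0L) return(NULL)
  a <- vecs[, i[1L]]
  Q <- matrix(c(a[1], a[2] / 2, a[2] / 2, a[3]), 2)
  ctr <- tryCatch(solve(Q, -c(a[4] / 2, a[5] / 2)), error = function(e) NULL)
  if (is.null(ctr)) return(NULL)
  k <- as.numeric(t(ctr) %*% Q %*% ctr) - a[6]
  if (k < 0) { Q <- -Q; k <- -k }
  if (k < 1e-12) return(NULL)
  Qn <- Q / k
  if (Qn[1, 1] <= 0 || det(Qn) <= 0) return(NULL)
  list(center = c(mx, my) + ctr * sc, Qn = Qn / sc^2)
}

# Normalized elliptical radius of query points (1 on the fitted boundary).
conic_radius <- function(fit, q) {
  d <- sweep(q, 2L, fit$center)
  sqrt(rowSums((d %*% fit$Qn) * d))
}

# Evaluate an expression with a fixed RNG seed, restoring the caller's stream.
with_rng_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Timestamped log line: "ISO8601 LEVEL stage message" (stderr + optional file).
log_msg <- function(stage, msg, level = "INFO", file = NULL) {
  line <- sprintf("%s %s %s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                  level, stage, msg)
  message(line)
  if (!is.null(file)) cat(line, "\n", sep = "", file = file, append = TRUE)
  invisible(line)
}
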