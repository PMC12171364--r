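# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never perturbs the
# user's stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Vectorised HSV -> RGB. h in degrees [0, 360), s and v in [0, 1].
# Returns an n x 3 matrix in [0, 1].
hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 360) / 60
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- g <- b <- numeric(length(h))
  sel <- function(k) i == k
  r[sel(0)] <- v[sel(0)]; g[sel(0)] <- t[sel(0)]; b[sel(0)] <- p[sel(0)]
  r[sel(1)] <- q[sel(1)]; g[sel(1)] <- v[sel(1)]; b[sel(1)] <- p[sel(1)]
  r[sel(2)] <- p[sel(2)]; g[sel(2)] <- v[sel(2)]; b[sel(2)] <- t[sel(2)]
  r[sel(3)] <- p[sel(3)]; g[sel(3)] <- q[sel(3)]; b[sel(3)] <- v[sel(3)]
  r[sel(4)] <- t[sel(4)]; g[sel(4)] <- p[sel(4)]; b[sel(4)] <- v[sel(4)]
  r[sel(5)] <- v[sel(5)]; g[sel(5)] <- p[sel(5)]; b[sel(5)] <- q[sel(5)]
  cbind(r, g, b)
}

# 8-connected component labelling of a logical matrix. Components are
# numbered 1..k in raster (column-major) order of their first pixel.
label_components_8 <- function(mask) {
  stopifnot(is.matrix(mask))
  H <- nrow(mask); W <- ncol(mask)
  fg <- which(mask)
  out <- matrix(0L, H, W)
  if (length(fg) == 0L) return(out)
  pos <- integer(H * W)
  pos[fg] <- seq_along(fg)
  rows <- ((fg - 1L) %% H) + 1L
  cols <- ((fg - 1L) %/% H) + 1L
  edges <- integer(0)
  # half the 8-neighbourhood; the other half is implied by symmetry
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    nr <- rows + d[1L]; nc <- cols + d[2L]
    ok <- nr >= 1L & nr <= H & nc >= 1L & nc <= W
    if (!any(ok)) next
    nidx <- (nc[ok] - 1L) * H + nr[ok]
    hit <- pos[nidx] > 0L
    if (any(hit)) {
      from <- pos[fg[ok]][hit]
      to <- pos[nidx][hit]
      edges <- c(edges, rbind(from, to))
    }
  }
  if (length(edges)) {
    g <- igraph::make_graph(edges, n = length(fg), directed = FALSE)
    memb <- igraph::components(g)$membership
  } else {
    memb <- seq_along(fg)
  }
  # renumber components by first pixel in raster order
  relab <- integer(max(memb))
  nxt <- 0L
  lab <- integer(length(fg))
  for (k in seq_along(fg)) {
    m <- memb[k]
    if (relab[m] == 0L) { nxt <- nxt + 1L; relab[m] <- nxt }
    lab[k] <- relab[m]
  }
  out[fg] <- lab
  out
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
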