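# Brute-force reference implementations, independent of the package's
# internals, used as oracles.

# shift a logical matrix by (dr, dc), padding with FALSE
shift_mask <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- intersect(seq_len(nr), seq_len(nr) - dr)
  cs <- intersect(seq_len(nc), seq_len(nc) - dc)
  out[rs + dr, cs + dc] <- m[rs, cs]
  out
}

# flood fill by iterated dilation-and-mask until fixed point
oracle_flood <- function(mask, seed_mask, connectivity = 4L) {
  offs <- if (connectivity == 4L)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  cur <- seed_mask & mask
  repeat {
    grown <- cur
    for (o in offs) grown <- grown | shift_mask(cur, o[1], o[2])
    grown <- grown & mask
    if (identical(grown, cur)) return(cur)
    cur <- grown
  }
}

# connected-component labelling by repeated oracle_flood from the first
# unlabelled pixel (scan order)
oracle_label <- function(mask, connectivity = 8L) {
  labels <- matrix(0L, nrow(mask), ncol(mask))
  lab <- 0L
  remaining <- mask
  while (any(remaining)) {
    seed <- matrix(FALSE, nrow(mask), ncol(mask))
    seed[which(remaining)[1L]] <- TRUE
    comp <- oracle_flood(remaining, seed, connectivity)
    lab <- lab + 1L
    labels[comp] <- lab
    remaining <- remaining & !comp
  }
  labels
}

# lumen candidates exactly as the spec describes: background = below-
# threshold pixels 4-connected to the border; lumina = remaining below-
# threshold components (8-connected)
oracle_lumen_labels <- function(values, thr) {
  below <- values < thr
  seed <- matrix(FALSE, nrow(values), ncol(values))
  seed[1, ] <- TRUE; seed[nrow(values), ] <- TRUE
  seed[, 1] <- TRUE; seed[, ncol(values)] <- TRUE
  bg <- oracle_flood(below, seed, 4L)
  oracle_label(below & !bg, 8L)
}

# independent Moore contour walk (complex-number bookkeeping) returning the
# chain-code perimeter of one 8-connected region
oracle_perimeter <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  px <- which(mask, arr.ind = TRUE)
  if (nrow(px) == 1L) return(4)
  zs <- complex(real = px[, 2], imaginary = px[, 1])
  start <- zs[order(Re(zs), Im(zs))][1L]  # leftmost column, then topmost
  on <- function(z) {
    r <- Im(z); c <- Re(z)
    r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c]
  }
  # clockwise in image coordinates (row grows downward): N, NE, E, SE, ...
  dirs <- complex(real = c(0, 1, 1, 1, 0, -1, -1, -1),
                  imaginary = c(-1, -1, 0, 1, 1, 1, 0, -1))
  cur <- start; d <- 1L; first_dir <- NA_integer_
  perim <- 0; moves <- 0L
  repeat {
    hit <- 0L
    for (k in 0:7) {
      dd <- ((d + k - 1L) %% 8L) + 1L
      if (on(cur + dirs[dd])) { hit <- dd; break }
    }
    if (hit == 0L) return(4)
    if (moves > 0L && cur == start && hit == first_dir) break
    if (is.na(first_dir)) first_dir <- hit
    perim <- perim + Mod(dirs[hit])
    cur <- cur + dirs[hit]
    d <- ((hit - 1L + 6L) %% 8L) + 1L
    moves <- moves + 1L
    if (moves > 8L * length(zs)) break
  }
  perim
}

# definition-following box stats (type-7 quartiles by hand)
oracle_box_stats <- function(x) {
  x <- sort(x)
  n <- length(x)
  qt <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  q1 <- qt(0.25); q3 <- qt(0.75); iqr <- q3 - q1
  inside <- x >= q1 - 1.5 * iqr & x <= q3 + 1.5 * iqr
  list(median = qt(0.5), q1 = q1, q3 = q3,
       whisker_low = min(x[inside]), whisker_high = max(x[inside]),
       outliers = x[!inside])
}

# two-sided permutation test for a difference in means
oracle_permutation_p <- function(a, b, n_perm = 20000L) {
  obs <- abs(mean(a) - mean(b))
  pool <- c(a, b)
  na <- length(a)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pool), na)
    if (abs(mean(pool[idx]) - mean(pool[-idx])) >= obs) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

# per-angular-sector maximum over every pixel of the annulus r +/- band
oracle_sector_max <- function(values, r0, c0, radius, band, n_sectors) {
  px <- which(values > -Inf, arr.ind = TRUE)
  d <- sqrt((px[, 1] - r0)^2 + (px[, 2] - c0)^2)
  keep <- abs(d - radius) <= band
  ang <- atan2(px[keep, 1] - r0, px[keep, 2] - c0) %% (2 * pi)
  sector <- floor(ang / (2 * pi / n_sectors)) + 1
  v <- values[px[keep, , drop = FALSE]]
  tapply(v, factor(sector, levels = seq_len(n_sectors)), max)
}

# random 16:0/18:1 chain-pair enumeration: exhaustive over ordered pairs
oracle_chain_null <- function(p16) {
  chains <- c("16:0", "18:1")
  probs <- c(p16, 1 - p16)
  out <- c(DP = 0, PO = 0, DO = 0)
  for (i in 1:2) for (j in 1:2) {
    cl <- if (chains[i] == chains[j]) {
      if (chains[i] == "16:0") "DP" else "DO"
    } else "PO"
    out[cl] <- out[cl] + probs[i] * probs[j]
  }
  100 * out
}
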