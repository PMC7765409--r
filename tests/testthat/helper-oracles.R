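# Independent brute-force oracles used to check the package's
# implementations on small inputs.

# Per-pixel nearest-nucleus ring oracle: for every pixel compute the exact
# Euclidean distance to every nucleus's pixel set; a cytoplasm pixel lies
# outside all nuclei, within `ring_width` of its nearest nucleus, and is
# assigned to that nucleus (ties -> lower label).
brute_ring <- function(labels, ring_width) {
  nr <- nrow(labels); nc <- ncol(labels)
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  best_d <- matrix(Inf, nr, nc)
  best_l <- matrix(0L, nr, nc)
  for (i in ids) {
    pix <- which(labels == i, arr.ind = TRUE)
    d <- matrix(Inf, nr, nc)
    for (k in seq_len(nrow(pix)))
      d <- pmin(d, sqrt((rr - pix[k, 1])^2 + (cc - pix[k, 2])^2))
    upd <- d < best_d - 1e-9
    best_d[upd] <- d[upd]
    best_l[upd] <- i
  }
  out <- best_l
  out[best_d <= 0 | best_d > ring_width] <- 0L
  out[labels > 0L] <- 0L
  out
}

# From-scratch greedy Ward clustering: at each step, evaluate the exact
# error-sum-of-squares increase of every candidate merge from the original
# squared distances (no Lance-Williams recurrence) and take the minimum,
# breaking ties by the lexicographically smallest leaf pair. Heights follow
# the distance-scaled convention h = sqrt(2 * dESS).
brute_ward <- function(d) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  clusters <- as.list(seq_len(n))
  sum_pairs <- function(A, B) sum(d2[A, B, drop = FALSE])
  cent2 <- function(A, B) {
    sum_pairs(A, B) / (length(A) * length(B)) -
      sum_pairs(A, A) / (2 * length(A)^2) -
      sum_pairs(B, B) / (2 * length(B)^2)
  }
  heights <- numeric(n - 1)
  parts <- vector("list", n - 1)
  for (m in seq_len(n - 1)) {
    best <- NULL
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in (i + 1):length(clusters)) {
        A <- clusters[[i]]; B <- clusters[[j]]
        dess <- (length(A) * length(B)) / (length(A) + length(B)) *
          cent2(A, B)
        key <- sort(c(min(A), min(B)))
        if (is.null(best) || dess < best$v - 1e-12 ||
            (abs(dess - best$v) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(v = dess, i = i, j = j, key = key)
        }
      }
    }
    heights[m] <- sqrt(max(2 * best$v, 0))
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    parts[[m]] <- merged
    clusters[[best$i]] <- merged
    clusters[[best$j]] <- NULL
  }
  list(heights = heights, members = parts)
}

# Members of the cluster formed at each merge of a ward_linkage, as sorted
# leaf index sets (comparable with brute_ward()$members).
linkage_members <- function(lk) {
  n <- nrow(lk$merge) + 1L
  out <- vector("list", n - 1L)
  for (m in seq_len(n - 1L)) {
    grab <- function(i) if (i < 0) -i else out[[i]]
    out[[m]] <- sort(c(grab(lk$merge[m, 1]), grab(lk$merge[m, 2])))
  }
  out
}

# Greedy one-to-one matching of detected nuclei to truth centers within a
# radius; returns indices into truth (NA = unmatched detection).
match_detections <- function(det, truth, max_dist = 5) {
  taken <- rep(FALSE, nrow(truth))
  m <- rep(NA_integer_, nrow(det))
  for (i in seq_len(nrow(det))) {
    d <- sqrt((truth$row - det$row[i])^2 + (truth$col - det$col[i])^2)
    d[taken] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= max_dist) {
      m[i] <- j
      taken[j] <- TRUE
    }
  }
  m
}

# Small standard field used by several imaging tests.
test_field <- function(seed = 1, noise = c(0, 0), n = 8, n_invalid = 2,
                       dim = c(384, 384)) {
  generate_field(field_params(dim = dim, n_nuclei = n,
                              n_invalid = n_invalid, noise_sd = noise),
                 seed = seed)
}
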