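# shared fixtures, built lazily and cached for the whole test run

.fixtures <- new.env(parent = emptyenv())

# small tumor block: 60 um box, a handful of cells
tiny_grid <- function() {
  if (is.null(.fixtures$tiny)) {
    cells <- place_cells(60, 5, seed = 101)
    .fixtures$tiny <- voxelize(cells, 60)
  }
  .fixtures$tiny
}

# the standard 0.2 mm / 1224-cell block used by the acceptance criteria
std_grid <- function() {
  if (is.null(.fixtures$std)) {
    cells <- place_cells(200, 1224, seed = 1)
    .fixtures$std <- voxelize(cells, 200)
  }
  .fixtures$std
}

# exact expectation of the misrejoining outcome by enumeration of all ordered
# Bernoulli trials with end blocking (tractable for N <= 3); independent of
# simulate_misrejoining()
enum_misrejoining <- function(positions, r0, p_nlmr = 0.5,
                              corrected_chains = FALSE) {
  n <- nrow(positions)
  d <- as.matrix(stats::dist(positions))
  pmat <- exp(-d / r0)
  trials <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) for (ei in 1:2) for (ej in 1:2)
    trials[[length(trials) + 1]] <- c(i, ei, j, ej)
  acc <- c(n_mr = 0, n_explicit = 0, surv = 0)
  rec <- function(t, prob, free, pairings) {
    if (t > length(trials)) {
      o <- structure(list(n_cdsb = n, n_explicit = nrow(pairings),
                          pairings = pairings),
                     class = "misrejoining_outcome")
      nmr <- count_misrejoinings(o, corrected_chains)
      acc[["n_mr"]] <<- acc[["n_mr"]] + prob * nmr
      acc[["n_explicit"]] <<- acc[["n_explicit"]] + prob * nrow(pairings)
      acc[["surv"]] <<- acc[["surv"]] + prob * p_nlmr^nmr
      return(invisible())
    }
    tr <- trials[[t]]
    if (!free[tr[1], tr[2]] || !free[tr[3], tr[4]]) {
      rec(t + 1, prob, free, pairings)
    } else {
      p <- pmat[tr[1], tr[3]]
      if (p > 0) {
        f2 <- free
        f2[tr[1], tr[2]] <- FALSE
        f2[tr[3], tr[4]] <- FALSE
        rec(t + 1, prob * p, f2,
            rbind(pairings, data.frame(i = tr[1], end_i = tr[2], j = tr[3],
                                       end_j = tr[4])))
      }
      if (p < 1) rec(t + 1, prob * (1 - p), free, pairings)
    }
  }
  rec(1, 1, matrix(TRUE, n, 2),
      data.frame(i = integer(0), end_i = integer(0), j = integer(0),
                 end_j = integer(0)))
  acc
}

# build a lesion-resolved site table by hand (for call_dsbs worked examples);
# each row: segment, chain, chain_pos, bp, strand, lesion
make_sites <- function(df, x = 0, y = 0, z = 0) {
  df$seg_x <- x + df$segment * 1e-3
  df$seg_y <- y
  df$seg_z <- z
  df$moiety <- ifelse(df$lesion == "modified_base", "base", "sugar")
  df$n_events <- 1L
  df
}

make_segments <- function(sites, tracks = "0") {
  segs <- unique(sites$segment)
  data.frame(segment = segs, n_events = 1L,
             track_ids = rep(tracks, length(segs)))
}

# outcome object from explicit pairings (for counting-rule worked cases)
make_outcome <- function(n, pairings) {
  structure(list(n_cdsb = n, n_explicit = nrow(pairings),
                 pairings = pairings),
            class = "misrejoining_outcome")
}
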