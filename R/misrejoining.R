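#' Misrejoining probability of two free-ends
#'
#' Negative exponential in the initial distance between the two complex DSBs
#' that produced the free-ends: \eqn{P_{mr} = e^{-d/r_0}}.
#'
#' @param d distance, micrometres (>= 0); vectorized.
#' @param r0 characteristic interaction distance, micrometres (> 0).
#' @return probability in (0, 1].
#' @examples
#' p_misrejoin(0.7, 0.7) # exp(-1)
#' @export
p_misrejoin <- function(d, r0) {
  if (any(d < 0)) stop("d must be >= 0", call. = FALSE)
  if (!is.numeric(r0) || length(r0) != 1L || r0 <= 0)
    stop("r0 must be a positive scalar", call. = FALSE)
  exp(-d / r0)
}

#' Simulate stochastic free-end misrejoining in one nucleus
#'
#' For N complex DSBs (cDSBs) the free-end combinations are tried once each in
#' a fixed order: for i < j, end 1 then end 2 of cDSB i against end 1 then end
#' 2 of cDSB j. A trial is attempted only when both ends are still free and
#' succeeds with probability \eqn{e^{-d_{ij}/r_0}} using the distance between
#' the two cDSB positions (both ends of a cDSB share its position). Success
#' binds both ends permanently. One uniform deviate is consumed per attempted
#' trial, in trial order.
#'
#' @param positions numeric matrix (N x 3) of cDSB positions, micrometres.
#' @param r0 characteristic interaction distance, micrometres.
#' @param seed integer seed.
#' @return an object of class \code{misrejoining_outcome}: list with
#'   \code{n_cdsb}, \code{n_explicit} (successful joins) and \code{pairings}
#'   (data frame i, end_i, j, end_j).
#' @export
simulate_misrejoining <- function(positions, r0, seed = 1) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  n <- nrow(positions)
  np <- 0L
  pi_ <- pei <- pj_ <- pej <- integer(if (n >= 2) n else 0)
  if (n >= 2) {
    u <- .u01(2L * n * (n - 1L), seed)
    nu <- 0L
    free <- matrix(TRUE, n, 2)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        dx <- positions[i, 1] - positions[j, 1]
        dy <- positions[i, 2] - positions[j, 2]
        dz <- positions[i, 3] - positions[j, 3]
        p <- exp(-sqrt(dx * dx + dy * dy + dz * dz) / r0)
        for (ei in 1:2) {
          for (ej in 1:2) {
            if (!free[i, ei] || !free[j, ej]) next
            nu <- nu + 1L
            if (u[nu] < p) {
              free[i, ei] <- FALSE
              free[j, ej] <- FALSE
              np <- np + 1L
              pi_[np] <- i; pei[np] <- ei; pj_[np] <- j; pej[np] <- ej
            }
          }
        }
      }
    }
  }
  len <- seq_len(np)
  structure(list(n_cdsb = n, n_explicit = np,
                 pairings = data.frame(i = pi_[len], end_i = pei[len],
                                       j = pj_[len], end_j = pej[len])),
            class = "misrejoining_outcome")
}

#' Count misrejoinings under the no-terminal-deletion assumptions
#'
#' Counting rules: every explicit join counts one misrejoining, except that
#' when two cDSBs explicitly joined both pairs of their ends together the
#' second join is not counted; cDSBs with a single misrejoined end contribute
#' nothing further (their other end is assumed to resolve within the exchange
#' chain, uncounted); cDSBs with both ends free restitute faithfully and
#' contribute zero. With \code{corrected_chains}, every closed exchange chain
#' of three or more cDSBs carrying the maximum number of explicit joins (a
#' cycle: both ends of every member bound) is counted as N - 1 instead of N.
#'
#' @param outcome a \code{misrejoining_outcome}.
#' @param corrected_chains apply the closed-chain N - 1 correction
#'   (default FALSE, matching the uncorrected published counting).
#' @return integer count \eqn{N_{mr}}.
#' @examples
#' o <- structure(list(n_cdsb = 2, n_explicit = 2,
#'                     pairings = data.frame(i = c(1, 1), end_i = c(1, 2),
#'                                           j = c(2, 2), end_j = c(1, 2))),
#'                class = "misrejoining_outcome")
#' count_misrejoinings(o) # 1: the second same-pair join is assumed, not counted
#' @export
count_misrejoinings <- function(outcome, corrected_chains = FALSE) {
  pr <- outcome$pairings
  if (nrow(pr) == 0) return(0L)
  ends <- c(pr$i * 2L + pr$end_i, pr$j * 2L + pr$end_j)
  if (anyDuplicated(ends))
    stop("inconsistent pairing graph: an end is joined twice", call. = FALSE)
  if (any(pr$i == pr$j))
    stop("inconsistent pairing graph: self-pairing", call. = FALSE)
  m <- max(pr$j) + 1L
  key <- pmin(pr$i, pr$j) * m + pmax(pr$i, pr$j)
  n_double <- sum(duplicated(key)) # an end pair can repeat at most once
  n_mr <- nrow(pr) - n_double
  if (corrected_chains) {
    # union-find over cDSBs joined by explicit pairings
    nodes <- sort(unique(c(pr$i, pr$j)))
    parent <- setNames(nodes, nodes)
    find <- function(x) {
      while (parent[[as.character(x)]] != x) x <- parent[[as.character(x)]]
      x
    }
    for (q in seq_len(nrow(pr))) {
      a <- find(pr$i[q]); b <- find(pr$j[q])
      if (a != b) parent[[as.character(a)]] <- b
    }
    comp <- vapply(nodes, find, 0)
    deg <- table(c(pr$i, pr$j))
    for (root in unique(comp)) {
      members <- nodes[comp == root]
      if (length(members) < 3) next
      # closed chain: every member has both ends bound (degree 2) and the
      # number of explicit joins equals the member count (a cycle carrying
      # the maximum number of joins)
      njoin <- sum(pr$i %in% members | pr$j %in% members)
      if (all(deg[as.character(members)] == 2L) && njoin == length(members))
        n_mr <- n_mr - 1L
    }
  }
  as.integer(n_mr)
}

#' Cell survival probability from counted misrejoinings
#'
#' Each counted misrejoining is independently non-lethal (a symmetric
#' exchange) with probability \code{p_nlmr}:
#' \eqn{P_{surv} = p_{nlmr}^{N_{mr}}}.
#'
#' @param n_mr counted misrejoinings (non-negative integer; vectorized).
#' @param p_nlmr probability a misrejoining is non-lethal, in (0, 1].
#' @return survival probability.
#' @examples
#' survival_probability(2, 0.5) # 0.25
#' @export
survival_probability <- function(n_mr, p_nlmr = 0.5) {
  if (any(n_mr < 0) || any(n_mr != round(n_mr)))
    stop("n_mr must be a non-negative integer", call. = FALSE)
  if (!is.numeric(p_nlmr) || length(p_nlmr) != 1L || p_nlmr <= 0 ||
      p_nlmr > 1)
    stop("p_nlmr must be in (0, 1]", call. = FALSE)
  p_nlmr^n_mr
}

#' Misrejoining and survival for many cells
#'
#' Runs \code{\link{simulate_misrejoining}} per cell on a table of cDSB
#' positions (child stream \code{child_seed(seed, cell_id, 4)}) and applies
#' the counting and survival rules.
#'
#' @param cdsb data frame with \code{cell_id, x_um, y_um, z_um} (one row per
#'   complex DSB).
#' @param cell_ids cells to report (cells without cDSBs get zero counts).
#' @param r0 characteristic interaction distance, micrometres.
#' @param p_nlmr non-lethal probability.
#' @param seed integer master seed.
#' @param corrected_chains see \code{\link{count_misrejoinings}}.
#' @return data frame: \code{cell_id, n_cdsb, n_explicit, n_mr, p_surv}.
#' @export
misrejoin_cells <- function(cdsb, cell_ids, r0 = 0.7, p_nlmr = 0.5, seed = 1,
                            corrected_chains = FALSE) {
  n <- length(cell_ids)
  out <- data.frame(cell_id = cell_ids, n_cdsb = 0L, n_explicit = 0L,
                    n_mr = 0L, p_surv = 1)
  if (nrow(cdsb)) {
    sp <- split(seq_len(nrow(cdsb)), cdsb$cell_id)
    for (cid in names(sp)) {
      k <- match(as.integer(cid), cell_ids)
      if (is.na(k)) next
      rows <- sp[[cid]]
      o <- simulate_misrejoining(
        as.matrix(cdsb[rows, c("x_um", "y_um", "z_um")]), r0,
        seed = child_seed(seed, as.integer(cid), 4))
      nmr <- count_misrejoinings(o, corrected_chains)
      out$n_cdsb[k] <- length(rows)
      out$n_explicit[k] <- o$n_explicit
      out$n_mr[k] <- nmr
      out$p_surv[k] <- survival_probability(nmr, p_nlmr)
    }
  }
  out
}
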