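#' Standard 10-20 scalp channel names
#'
#' The 19 electrode names of the international 10-20 system in the fixed
#' order used throughout the package: `Fp1, Fp2, F7, F3, Fz, F4, F8, T3, C3,
#' Cz, C4, T4, T5, P3, Pz, P4, T6, O1, O2`.
#'
#' @return Character vector of length 19.
#' @export
#' @examples
#' tenTwentyChannels()
tenTwentyChannels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
    "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Adjacency of the 10-20 electrode layout
#'
#' A symmetric 19x19 0/1 matrix linking spatially neighbouring electrodes on
#' the standard scalp grid (rows front-to-back: Fp, F, C/T, P/T, O). Used by
#' the synthetic generator to attenuate planted discharges with graph
#' distance from the focal channels.
#'
#' @return Symmetric integer matrix with dimnames [tenTwentyChannels()].
#' @export
tenTwentyAdjacency <- function() {
  ch <- tenTwentyChannels()
  edges <- list(
    c("Fp1", "Fp2"), c("Fp1", "F7"), c("Fp1", "F3"), c("Fp1", "Fz"),
    c("Fp2", "F4"), c("Fp2", "F8"), c("Fp2", "Fz"),
    c("F7", "F3"), c("F3", "Fz"), c("Fz", "F4"), c("F4", "F8"),
    c("F7", "T3"), c("F3", "C3"), c("Fz", "Cz"), c("F4", "C4"), c("F8", "T4"),
    c("T3", "C3"), c("C3", "Cz"), c("Cz", "C4"), c("C4", "T4"),
    c("T3", "T5"), c("C3", "P3"), c("Cz", "Pz"), c("C4", "P4"), c("T4", "T6"),
    c("T5", "P3"), c("P3", "Pz"), c("Pz", "P4"), c("P4", "T6"),
    c("T5", "O1"), c("P3", "O1"), c("Pz", "O1"), c("Pz", "O2"),
    c("P4", "O2"), c("T6", "O2"), c("O1", "O2")
  )
  A <- matrix(0L, 19L, 19L, dimnames = list(ch, ch))
  for (e in edges) {
    A[e[1], e[2]] <- 1L
    A[e[2], e[1]] <- 1L
  }
  A
}

#' Graph distance from a set of channels
#'
#' Breadth-first hop count on the 10-20 adjacency from the nearest member of
#' `from`; channels unreachable from `from` get `Inf` (cannot happen on the
#' connected standard layout).
#'
#' @param from Character vector of seed channel names.
#' @return Named integer vector of hop distances over all 19 channels.
#' @keywords internal
channelDistance <- function(from) {
  ch <- tenTwentyChannels()
  stopifnot(all(from %in% ch))
  A <- tenTwentyAdjacency()
  d <- rep(Inf, 19L)
  names(d) <- ch
  d[from] <- 0
  frontier <- from
  hop <- 0
  while (length(frontier)) {
    hop <- hop + 1
    nxt <- character(0)
    for (f in frontier) {
      nb <- ch[A[f, ] == 1L & d > hop]
      d[nb] <- hop
      nxt <- c(nxt, nb)
    }
    frontier <- unique(nxt)
  }
  d
}

#' Names of the seven epileptiform discharge types
#'
#' @return Character vector: spike, sharp, spike_slow, sharp_slow, polyspike,
#'   polyspike_slow, spike_rhythm.
#' @export
dischargeTypes <- function() {
  c("spike", "sharp", "spike_slow", "sharp_slow",
    "polyspike", "polyspike_slow", "spike_rhythm")
}

#' Clinical per-type epoch counts used as the default synthetic catalog
#'
#' The default number of epochs generated per discharge type, mirroring the
#' per-type composition of the cohort the method was developed on
#' (69 spikes, 82 sharps, 174 spike-and-slow-wave, 72 sharp-and-slow-wave,
#' 64 polyspike, 77 polyspike-and-slow-wave, 2 spike rhythm; total 540).
#'
#' @return Named integer vector over [dischargeTypes()].
#' @export
defaultTypeCounts <- function() {
  stats::setNames(c(69L, 82L, 174L, 72L, 64L, 77L, 2L), dischargeTypes())
}
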