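# Published simulation-study protocol at full scale.

#' Full-scale simulation protocol
#'
#' The complete operating point of the simulation study at acquisition
#' scale: 216 x 216 in-plane matrix, 432 read-out samples per spoke (2x
#' radial oversampling), 34 golden-angle spokes per flip-angle encoding
#' continued across encodings, 10 flip angles 1-19 degrees in steps of 2,
#' TR = 5.38 ms, 7 Biot-Savart coils, 13 Gauss-Newton steps with
#' 100/200/300 inner iterations, and the trained regularization schedules.
#' Undersampling levels follow the Fibonacci series (34, 21, 13, 8 spokes).
#'
#' This configuration is an extended (hours-long, single CPU) experiment:
#' the desk-scale studies in the package tests use the same generator and
#' reconstruction code on reduced grids.  `scripts/extended_simulation.R`
#' runs it end to end.
#'
#' @param n_slices number of simulated slices.
#' @param spokes spokes per encoding (a Fibonacci number).
#' @return list with `shape`, `spokes`, `fibonacci_spokes`,
#'   `flip_angles_deg`, `tr_ms`, `n_coils`, `samples_per_spoke`, and a
#'   ready [irgn_config()] as `config`.
#' @export
fullscale_protocol <- function(n_slices = 8, spokes = 34) {
  stopifnot(spokes %in% c(8, 13, 21, 34, 55, 89))
  list(shape = c(216L, 216L, as.integer(n_slices)),
       spokes = as.integer(spokes),
       fibonacci_spokes = c(34L, 21L, 13L, 8L),
       flip_angles_deg = seq(1, 19, by = 2),
       tr_ms = 5.38,
       n_coils = 7L,
       samples_per_spoke = 432L,
       config = irgn_config(gn_steps = 13, pd_iters = c(100, 200, 300),
                            profile = "numerical_phantom"))
}
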