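## Parameter-recovery studies on the surrogate landscapes ---------------------
##
## These drivers re-run the full enhanced-sampling pipelines on the synthetic
## landscapes and measure how well the constructed free-energy layout is
## recovered.  They are what the acceptance checks and the reproduction
## script execute; run lengths are convergence-based choices documented in
## the methods vignette.

#' Recover the reaction free-energy layout by well-tempered metadynamics
#'
#' Runs well-tempered metadynamics with the beta-elimination hill schedule
#' (widths 0.15 A x 0.15 A, reference height 1.0 kcal/mol, well-tempered
#' parameter 30 kcal/mol, one hill every 100 steps) on the surrogate
#' reaction landscape, reconstructs the free-energy surface from the
#' accumulated bias (time-averaged over the final 60% of the deposition),
#' extracts the minimum free-energy path between the recovered MC and PC
#' basins and measures the activation and reaction free energies.
#'
#' @param seeds integer vector of seeds; results are averaged.
#' @param n_hills hills per run.
#' @param average_fraction tail fraction of the hill history averaged in the
#'   reconstruction.
#' @return list with `dg_act`, `dg_rxn` (seed means), `per_seed` (matrix) and
#'   `ts` (mean recovered saddle position).
#' @export
recover_reaction_landscape <- function(seeds = 1:3, n_hills = 20000,
                                       average_fraction = 0.6) {
  pot <- build_surrogate_reaction_landscape()
  axes <- list(seq(-1.9, 2.8, length.out = 101),
               seq(-0.55, 4.45, length.out = 101))
  per <- vapply(seeds, function(s) {
    md <- run_metadynamics(pot, x0 = c(-1, 1.1), n_hills = n_hills,
                           stride = 100, sigma = c(0.15, 0.15), h0 = 1.0,
                           delta_T = 30, seed = s)
    fes <- reconstruct_fes(md$bias, axes, average_fraction = average_fraction)
    m <- find_minima(fes, depth_floor = 2)
    mc <- m[which.min((m$cv1 + 1)^2 + (m$cv2 - 1.1)^2), ]
    pc <- m[which.min((m$cv1 - 1.8)^2 + (m$cv2 - 3.4)^2), ]
    path <- find_mfep(fes, mc, pc)
    bd <- barrier_and_dg(path)
    ts <- path[attr(path, "saddle"), ]
    ## intermediate stability as a small-disc average (robust to the
    ## extreme-value bias of single noisy grid cells)
    disc <- function(c1, c2, r = 0.1) {
      th <- seq(0, 2 * pi, length.out = 13)[-13]
      mean(fes_at(fes, cbind(c1 + r * cos(th), c2 + r * sin(th))))
    }
    ic <- disc(1.8, 1.7) - disc(-1, 1.1)
    c(bd$dg_act, bd$dg_rxn, ts$cv1, ts$cv2, ic)
  }, numeric(5))
  list(dg_act = mean(per[1, ]), dg_rxn = mean(per[2, ]),
       ts = c(cv1 = mean(per[3, ]), cv2 = mean(per[4, ])),
       ic_rel_mc = mean(per[5, ], na.rm = TRUE),
       per_seed = per)
}

#' Recover the refined barrier by umbrella sampling and WHAM
#'
#' Places the nine-window protocol (CV1 = -0.75 to 1.25 A in 0.25 A steps)
#' on the surrogate 1D profile, samples each window with an overdamped
#' Langevin run under a stiff harmonic restraint, solves the WHAM equations
#' and measures the barrier of the resulting potential of mean force.
#'
#' @param seeds integer vector of seeds; barriers are averaged.
#' @param k restraint force constant (kcal/mol/A^2).
#' @param n_steps steps per window (the first third is discarded).
#' @return list with `barrier` (seed mean), `per_seed`, and the window
#'   centres used.
#' @export
recover_us_barrier <- function(seeds = 1:3, k = 200, n_steps = 250000) {
  us <- build_surrogate_us_profile()
  centers <- make_windows(-0.75, 1.25, 0.25)
  per <- vapply(seeds, function(s) {
    wins <- lapply(seq_along(centers), function(i)
      sample_window(us, centers[i], k = k, n_steps = n_steps, friction = 10,
                    seed = s * 100 + i))
    pmf <- wham_solve(wins, n_bins = 201)
    pmf_barrier(pmf, min_count = 200, smooth = 6)
  }, numeric(1))
  list(barrier = mean(per), per_seed = per, centers = centers)
}

#' Recover the conformational free-energy gaps by puckering metadynamics
#'
#' Runs well-tempered metadynamics on the periodic (phi, theta) surrogate
#' with the conformational hill schedule (widths 0.1 rad x 0.1 rad,
#' reference height 0.5 kcal/mol, well-tempered parameter 15 kcal/mol) and
#' measures the free-energy of the 5S1 and OS2 wells relative to the 1C4
#' polar trench on the reconstructed surface.
#'
#' @param seeds integer vector of seeds; gaps are averaged.
#' @param n_hills hills per run.
#' @param average_fraction tail fraction averaged in the reconstruction.
#' @return list with `gap_5S1`, `gap_OS2` (seed means, kcal/mol) and
#'   `per_seed`.
#' @export
recover_pucker_gaps <- function(seeds = 1:5, n_hills = 60000,
                                average_fraction = 0.8) {
  pk <- build_surrogate_pucker_landscape()
  ## evaluate the (time-averaged) estimator only where it is needed: along
  ## the 1C4 polar trench and on small discs at the two well positions
  trench <- cbind(seq(0, 2 * pi, length.out = 121)[-121], pi)
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  disc_pts <- function(c1, c2) cbind(c1 + 0.05 * cos(th), c2 + 0.05 * sin(th))
  pts <- rbind(trench, disc_pts(pi / 2, pi / 2), disc_pts(11 * pi / 6, pi / 2))
  i_tr <- seq_len(nrow(trench))
  i_5 <- nrow(trench) + seq_along(th)
  i_O <- nrow(trench) + length(th) + seq_along(th)
  per <- vapply(seeds, function(s) {
    md <- run_metadynamics(pk, x0 = c(0, 1.3), n_hills = n_hills,
                           stride = 100, sigma = c(0.1, 0.1), h0 = 0.5,
                           delta_T = 15, seed = s, grid_bias = TRUE)
    F <- fes_estimate_at(md$bias, pts, average_fraction = average_fraction)
    f1 <- mean(F[i_tr])      # the trench is flat in phi: average along it
    c(mean(F[i_5]) - f1, mean(F[i_O]) - f1)
  }, numeric(2))
  list(gap_5S1 = mean(per[1, ]), gap_OS2 = mean(per[2, ]), per_seed = per)
}
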