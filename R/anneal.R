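# Restrained simulated annealing in torsion space. Rings are rigid 4C1
# bodies, so the degrees of freedom are the glycosidic (phi, psi) torsions
# plus the GalNAc exocyclic torsions; sampling is Metropolis Monte Carlo with
# Gaussian single-torsion moves whose width shrinks linearly with
# temperature (30 degrees at 500 K down to 2 degrees near 0 K), followed by
# a zero-temperature greedy quench in place of a gradient minimisation.

#' Annealing schedule
#'
#' Linear heat - hold - cool temperature profile: `t_start` to `t_max` over
#' `heat_steps`, `hold_steps` at `t_max`, then down to `t_end` over
#' `cool_steps`; `moves_per_step` Monte-Carlo moves are attempted at each
#' temperature, and `quench_moves` greedy (downhill-only) moves finish the
#' round.
#'
#' @param heat_steps,hold_steps,cool_steps Temperature steps per phase.
#' @param moves_per_step Monte-Carlo moves per temperature step.
#' @param t_start,t_max,t_end Temperatures in kelvin (1, 500, 0 by default).
#' @param quench_moves Greedy moves after cooling.
#' @param polish_maxit Iteration budget of the derivative-free simplex
#'   polish that follows the greedy quench (0 disables it).
#' @return An `anneal_schedule` list.
#' @export
anneal_schedule <- function(heat_steps = 50, hold_steps = 50,
                            cool_steps = 100, moves_per_step = 2,
                            t_start = 1, t_max = 500, t_end = 0,
                            quench_moves = 200, polish_maxit = 1200) {
  stopifnot(heat_steps >= 0, hold_steps >= 0, cool_steps >= 0,
            moves_per_step >= 1, t_start >= 0, t_max >= t_start, t_end >= 0,
            quench_moves >= 0, polish_maxit >= 0)
  structure(list(heat_steps = heat_steps, hold_steps = hold_steps,
                 cool_steps = cool_steps, moves_per_step = moves_per_step,
                 t_start = t_start, t_max = t_max, t_end = t_end,
                 quench_moves = quench_moves, polish_maxit = polish_maxit),
            class = "anneal_schedule")
}

temperature_profile <- function(s) {
  heat <- if (s$heat_steps > 0) {
    seq(s$t_start, s$t_max, length.out = s$heat_steps)
  } else {
    numeric(0)
  }
  hold <- rep(s$t_max, s$hold_steps)
  cool <- if (s$cool_steps > 0) {
    seq(s$t_max, s$t_end, length.out = s$cool_steps)
  } else {
    numeric(0)
  }
  c(heat, hold, cool)
}

# proposal width: 30 degrees at 500 K shrinking linearly to 2 degrees at 0 K
move_sigma <- function(temperature) 2 + 28 * pmin(1, temperature / 500)

# flatten/unflatten the sampled torsion parameters
par_to_vec <- function(par) c(par$phi, par$psi, par$omega, par$acetamido)

vec_to_par <- function(v, par) {
  n_link <- length(par$phi)
  n_gal <- length(par$omega)
  list(phi = v[seq_len(n_link)],
       psi = v[n_link + seq_len(n_link)],
       omega = v[2 * n_link + seq_len(n_gal)],
       acetamido = v[2 * n_link + n_gal + seq_len(n_gal)])
}

# fast objective used inside the MC loop: restraint + steric terms. The ring
# term is identically zero for rigid templates and is added back (for
# reporting) through total_energy() at the end of the round.
mc_energy <- function(topo, v, par0, ridx, lower, upper, emodel, k_restraint) {
  xyz <- chain_coords(topo, vec_to_par(v, par0))
  r <- restraint_energy_xyz(xyz, ridx, lower, upper, k_restraint)
  st <- steric_energy_xyz(xyz, topo$steric_pairs, emodel$steric_k,
                          emodel$steric_cutoff)
  list(energy = r$energy + st, max_violation = max(r$violations))
}

#' One round of restrained simulated annealing
#'
#' Runs the heat/hold/cool Metropolis schedule from the starting model's
#' torsions and finishes with a greedy quench followed by a derivative-free
#' simplex polish (the stand-in for a gradient minimisation). Deterministic
#' for a fixed seed.
#'
#' @param start_model A `glycan_model` (the starting conformation).
#' @param restraints Restraint tibble (see [build_restraint_set()]).
#' @param schedule An [anneal_schedule()].
#' @param emodel An [energy_model()].
#' @param seed Integer seed for the round.
#' @return A list with `model` (the final `glycan_model`), `energy`
#'   (kcal/mol, including the ring term), `max_violation` (angstroms) and
#'   `accepted` (move acceptance count).
#' @export
anneal_once <- function(start_model, restraints, schedule = anneal_schedule(),
                        emodel = energy_model(), seed = 1) {
  topo <- model_topology(start_model)
  par0 <- attr(start_model, "par")
  ridx <- restraint_indices(topo, restraints)
  lower <- restraints$lower
  upper <- restraints$upper
  k_r <- if ("force_constant" %in% names(restraints)) {
    restraints$force_constant
  } else {
    emodel$restraint_k
  }

  v <- par_to_vec(par0)
  n_par <- length(v)

  result <- with_seed(seed, {
    cur <- mc_energy(topo, v, par0, ridx, lower, upper, emodel, k_r)
    accepted <- 0L
    temps <- temperature_profile(schedule)
    for (temp in temps) {
      sigma <- move_sigma(temp)
      kt <- R_GAS * temp
      for (m in seq_len(schedule$moves_per_step)) {
        j <- sample.int(n_par, 1)
        trial <- v
        trial[j] <- wrap_angle(trial[j] + stats::rnorm(1, 0, sigma))
        cand <- mc_energy(topo, trial, par0, ridx, lower, upper, emodel, k_r)
        de <- cand$energy - cur$energy
        if (de <= 0 || (kt > 0 && stats::runif(1) < exp(-de / kt))) {
          v <- trial
          cur <- cand
          accepted <- accepted + 1L
        }
      }
    }
    # greedy quench: downhill-only, shrinking step
    for (m in seq_len(schedule$quench_moves)) {
      sigma <- if (m <= schedule$quench_moves / 2) 2 else 0.5
      j <- sample.int(n_par, 1)
      trial <- v
      trial[j] <- wrap_angle(trial[j] + stats::rnorm(1, 0, sigma))
      cand <- mc_energy(topo, trial, par0, ridx, lower, upper, emodel, k_r)
      if (cand$energy < cur$energy) {
        v <- trial
        cur <- cand
        accepted <- accepted + 1L
      }
    }
    list(v = v, accepted = accepted)
  })

  v <- result$v
  if (schedule$polish_maxit > 0) {
    # derivative-free simplex polish of the quenched torsions (deterministic)
    opt <- stats::optim(
      v,
      function(x) {
        mc_energy(topo, x, par0, ridx, lower, upper, emodel, k_r)$energy
      },
      method = "Nelder-Mead",
      control = list(maxit = schedule$polish_maxit, reltol = 1e-12)
    )
    cand <- mc_energy(topo, opt$par, par0, ridx, lower, upper, emodel, k_r)
    base <- mc_energy(topo, v, par0, ridx, lower, upper, emodel, k_r)
    if (cand$energy <= base$energy) v <- wrap_angle(opt$par)
  }
  result$v <- v

  final_par <- vec_to_par(result$v, par0)
  model <- new_glycan_model(topo, final_par)
  te <- total_energy(model, restraints, emodel)
  list(model = model, energy = te$energy,
       max_violation = te$max_violation, accepted = result$accepted)
}

new_conformer_ensemble <- function(tbl, n_generated, kept_fraction, seed) {
  tibble::new_tibble(
    tbl, nrow = nrow(tbl), class = "conformer_ensemble",
    n_generated = n_generated, kept_fraction = kept_fraction,
    ensemble_seed = seed
  )
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat("<conformer_ensemble> ", nrow(x), " of ", attr(x, "n_generated"),
      " models kept (fraction ", attr(x, "kept_fraction"), ")\n", sep = "")
  NextMethod()
}

ensemble_models <- function(ensemble) {
  if (inherits(ensemble, "conformer_ensemble") ||
      (is.data.frame(ensemble) && "model" %in% names(ensemble))) {
    return(ensemble$model)
  }
  if (is.list(ensemble)) return(ensemble)
  stop("cannot interpret ensemble input", call. = FALSE)
}

#' Generate an energy-ranked conformer ensemble
#'
#' Runs `n_rounds` independent annealing rounds (round `i` uses seed
#' `seed + i - 1`) and keeps the lowest-energy fraction, sorted ascending by
#' energy with ties broken by round index.
#'
#' @param start_model Starting `glycan_model`.
#' @param restraints Restraint tibble.
#' @param n_rounds Number of annealing rounds (default 250).
#' @param keep_fraction Fraction of models kept (default 0.10, i.e. 25 of
#'   250).
#' @param schedule An [anneal_schedule()].
#' @param emodel An [energy_model()].
#' @param seed Base integer seed.
#' @return A `conformer_ensemble`: tibble with columns `rank`, `round`,
#'   `energy`, `max_violation` and `model` (list of `glycan_model`s), sorted
#'   by energy. Attributes `n_generated`, `kept_fraction`, `ensemble_seed`.
#' @export
generate_ensemble <- function(start_model, restraints, n_rounds = 250,
                              keep_fraction = 0.10,
                              schedule = anneal_schedule(),
                              emodel = energy_model(), seed = 1) {
  stopifnot(n_rounds >= 1, keep_fraction > 0, keep_fraction <= 1)
  rounds <- purrr::map(seq_len(n_rounds), function(i) {
    r <- anneal_once(start_model, restraints, schedule, emodel,
                     seed = seed + i - 1)
    tibble::tibble(round = i, energy = r$energy,
                   max_violation = r$max_violation, model = list(r$model))
  })
  all <- dplyr::bind_rows(rounds)
  keep <- max(1, round(keep_fraction * n_rounds))
  ord <- order(all$energy, all$round)   # ties broken by round index
  kept <- all[ord[seq_len(keep)], ]
  kept$rank <- seq_len(nrow(kept))
  kept <- dplyr::select(kept, "rank", "round", "energy", "max_violation",
                        "model")
  new_conformer_ensemble(kept, n_generated = n_rounds,
                         kept_fraction = keep_fraction, seed = seed)
}
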