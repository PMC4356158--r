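#' Population state for the genotype-class Wright-Fisher simulator
#'
#' The population is represented as genotype classes rather than
#' individuals: parallel vectors of fitness and abundance plus a list of
#' model-specific payloads.  Class counts always sum to the population
#' size N, and empty classes are pruned after every step.  This keeps
#' populations of size \eqn{10^6} tractable while remaining statistically
#' equivalent to a per-individual simulation (a tested property, see the
#' package tests).
#'
#' @param classes a list of [genotype_class()] objects whose counts sum
#'   to \code{N}.
#' @param N total population size.
#' @param generation current generation (0 at founding).
#' @return A \code{population_state} object with fields \code{w}
#'   (numeric), \code{count} (numeric), \code{state} (list),
#'   \code{N}, \code{generation}.
#' @export
population_state <- function(classes, N, generation = 0L) {
  if (!length(classes)) stop("classes must be non-empty")
  w <- vapply(classes, function(cl) cl$w, numeric(1))
  count <- vapply(classes, function(cl) cl$count, numeric(1))
  state <- lapply(classes, function(cl) cl$state)
  if (any(w <= 0)) stop("all class fitness values must be positive")
  if (any(count < 0)) stop("class counts must be non-negative")
  if (sum(count) != N)
    stop("class counts must sum to N (", sum(count), " != ", N, ")")
  keep <- count > 0
  structure(list(w = w[keep], count = count[keep], state = state[keep],
                 N = as.numeric(N), generation = as.integer(generation)),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat("<population_state> N =", x$N, "generation =", x$generation,
      "classes =", length(x$w), "mean w =",
      signif(mean_fitness(x), 6), "\n")
  invisible(x)
}

#' Population mean fitness
#' @param pop a \code{population_state}.
#' @return The abundance-weighted mean fitness.
#' @export
mean_fitness <- function(pop) sum(pop$count * pop$w) / pop$N

#' Wright-Fisher selection step
#'
#' Multinomial resampling of N offspring among the genotype classes with
#' probabilities proportional to \eqn{count_i \cdot w_i}; the discrete
#' non-overlapping-generation scheme standard for serial-transfer
#' experiments.  Population size is exactly conserved and extinct
#' classes are pruned.
#'
#' @param pop a \code{population_state} with at least one individual.
#' @return The post-selection \code{population_state} (generation
#'   unchanged; [run_simulation()] increments it after the paired
#'   mutation step).
#' @export
selection_step <- function(pop) {
  if (!inherits(pop, "population_state")) stop("pop must be a population_state")
  if (sum(pop$count) <= 0) stop("population is empty")
  wsum <- pop$count * pop$w
  newc <- as.numeric(stats::rmultinom(1, pop$N, wsum / sum(wsum)))
  keep <- newc > 0
  pop$w <- pop$w[keep]
  pop$count <- newc[keep]
  pop$state <- pop$state[keep]
  pop
}

#' Mutation step under a macroscopic-epistasis model
#'
#' For each genotype class, the number of mutating individuals is drawn
#' binomially with per-individual probability
#' \code{beneficial_rate(model, w)}; each mutation event founds a new
#' class of count 1 via [draw_mutant()], and its parent class shrinks by
#' one.  Multiple mutations in one individual in one generation are
#' ignored (at rates of order \eqn{10^{-5}} doubles are of order
#' \eqn{10^{-10}}).  N is conserved exactly.
#'
#' @param pop a \code{population_state}.
#' @param model a \code{model_spec}.
#' @return The post-mutation \code{population_state}.
#' @export
mutation_step <- function(pop, model) {
  if (!inherits(pop, "population_state")) stop("pop must be a population_state")
  rate <- beneficial_rate(model, pop$w)
  nmut <- stats::rbinom(length(pop$count), pop$count, rate)
  hit <- which(nmut > 0)
  if (!length(hit)) return(pop)
  new_w <- vector("list", length(hit))
  new_state <- vector("list", length(hit))
  for (h in seq_along(hit)) {
    i <- hit[h]
    drawn <- draw_mutants(model, pop$w[i], pop$state[[i]], nmut[i])
    new_w[[h]] <- drawn$w
    new_state[[h]] <- drawn$state
  }
  pop$w <- c(pop$w, unlist(new_w))
  pop$count <- c(pop$count, rep.int(1, sum(nmut[hit])))
  pop$state <- c(pop$state, do.call(c, new_state))
  pop$count[hit] <- pop$count[hit] - nmut[hit]
  keep <- pop$count > 0
  pop$w <- pop$w[keep]
  pop$count <- pop$count[keep]
  pop$state <- pop$state[keep]
  pop
}

# batch form of draw_mutant used by the hot loop: k mutants of one parent.
# Returns list(w = numeric(k), state = list of k payloads).
draw_mutants <- function(model, w_parent, state_parent, k) {
  p <- model$params
  switch(model$kind,
    diminishing_effects = {
      s <- stats::rexp(k, rate = p$alpha0 * w_parent^p$g)
      list(w = w_parent * (1 + s), state = vector("list", k))
    },
    declining_rate = {
      s <- stats::rexp(k, rate = p$alpha)
      list(w = w_parent * (1 + s), state = vector("list", k))
    },
    finite_sites = {
      free <- setdiff(seq_len(p$L), state_parent)
      w <- numeric(k)
      st <- vector("list", k)
      for (j in seq_len(k)) {
        if (length(free) == 0) {
          w[j] <- w_parent
          st[[j]] <- state_parent
        } else {
          site <- if (length(free) == 1) free else sample(free, 1)
          w[j] <- w_parent * (1 + p$site_effects[site])
          st[[j]] <- c(state_parent, site)
        }
      }
      list(w = w, state = st)
    },
    fgm = {
      dz <- matrix(stats::rnorm(k * p$n, sd = p$sigma), nrow = k)
      z2 <- sweep(dz, 2, state_parent, "+")
      list(w = fgm_fitness(z2),
           state = lapply(seq_len(k), function(j) z2[j, ]))
    }
  )
}

#' Simulation configuration
#'
#' @param N population size (default \eqn{10^6}; together with the
#'   default baseline mutation rate \eqn{10^{-5}} this puts the
#'   population in the clonal-interference regime, \eqn{N\mu = 10}).
#' @param mu baseline per-individual beneficial mutation rate.  When
#'   given it overrides the model's baseline (\code{mu}, or \code{mu0}
#'   for the declining-rate model) so configuration and model cannot
#'   disagree; when omitted it is taken from the model.
#' @param T total generations to simulate.
#' @param model a \code{model_spec}.
#' @param seed RNG seed (mandatory: replicate r of a run uses
#'   \code{seed + r}).
#' @param record_every recording interval, in generations, for the mean
#'   fitness trajectory.
#' @param replicates number of independent replicate runs.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(model, N = 1e6, mu = NULL, T = 500, seed,
                       record_every = 10L, replicates = 1L) {
  stopifnot(inherits(model, "model_spec"))
  if (missing(seed) || !is.numeric(seed))
    stop("an integer RNG seed is required")
  if (N < 1 || T < 1 || replicates < 1 || record_every < 1)
    stop("N, T, replicates and record_every must be positive")
  rate_field <- if (model$kind == "declining_rate") "mu0" else "mu"
  if (is.null(mu)) {
    mu <- model$params[[rate_field]]
  } else {
    if (mu < 0 || mu > 1) stop("mu must lie in [0, 1]")
    model$params[[rate_field]] <- mu
  }
  structure(list(N = N, mu = mu, T = as.integer(T), model = model,
                 seed = as.integer(seed),
                 record_every = as.integer(record_every),
                 replicates = as.integer(replicates)),
            class = "sim_config")
}

#' Run one simulation and record the mean-fitness trajectory
#'
#' Alternates [selection_step()] and [mutation_step()] for \code{T}
#' generations starting from a monomorphic founder, recording the
#' population mean fitness every \code{record_every} generations
#' (plus generation 0 and T).  Identical seed and configuration give a
#' bit-identical trajectory.
#'
#' @param config a [sim_config()].
#' @param founder a [genotype_class()]; its count is set to N.
#' @param seed optional seed overriding \code{config$seed} (used by
#'   [run_experiment()] for replicate seeding).
#' @return A data frame of class \code{fitness_trajectory} with columns
#'   \code{generation}, \code{mean_w}, plus attribute \code{final_w}.
#' @export
run_simulation <- function(config, founder, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"),
            inherits(founder, "genotype_class"))
  set.seed(seed)
  founder$count <- config$N
  pop <- population_state(list(founder), config$N)
  rec_at <- unique(c(seq(0, config$T, by = config$record_every), config$T))
  gens <- numeric(length(rec_at))
  mw <- numeric(length(rec_at))
  gens[1] <- 0
  mw[1] <- mean_fitness(pop)
  j <- 2L
  for (t in seq_len(config$T)) {
    pop <- selection_step(pop)
    pop <- mutation_step(pop, config$model)
    pop$generation <- t
    if (j <= length(rec_at) && t == rec_at[j]) {
      gens[j] <- t
      mw[j] <- mean_fitness(pop)
      j <- j + 1L
    }
  }
  out <- data.frame(generation = gens, mean_w = mw)
  class(out) <- c("fitness_trajectory", "data.frame")
  attr(out, "final_w") <- mw[length(mw)]
  out
}

#' Replicated evolution experiment across a founder ladder
#'
#' The in-silico analogue of the evolve-and-compare experimental design:
#' each founder (spanning a range of initial fitness) is evolved in
#' \code{reps} independent replicate runs, and the across-replicate mean
#' final fitness is reported as that founder's final fitness.  The
#' result feeds [standardize()] and the regression stage unchanged.
#'
#' Replicate r of founder f uses seed
#' \code{config$seed + (f-1)*reps + r}, so founders and replicates are
#' independent but jointly reproducible.
#'
#' @param founders a list of [genotype_class()] founders with distinct
#'   fitness (e.g. from [founder_ladder()]).
#' @param config a [sim_config()]; its \code{replicates} field is
#'   overridden by \code{reps}.
#' @param reps replicates per founder (default \code{config$replicates}).
#' @return A \code{fitness_records} data frame with one row per founder
#'   (\code{w_start} = founder fitness, \code{w_final} =
#'   across-replicate mean final fitness, scale \code{"relative"}).
#'   Per-replicate final fitness is attached as attribute
#'   \code{"replicate_finals"} (a founders x reps matrix).
#' @export
run_experiment <- function(founders, config, reps = config$replicates) {
  stopifnot(inherits(config, "sim_config"), length(founders) > 0,
            reps >= 1)
  finals <- matrix(NA_real_, nrow = length(founders), ncol = reps)
  for (f in seq_along(founders)) {
    for (r in seq_len(reps)) {
      traj <- run_simulation(config, founders[[f]],
                             seed = config$seed + (f - 1L) * reps + r)
      finals[f, r] <- attr(traj, "final_w")
    }
  }
  ids <- sprintf("founder_%02d", seq_along(founders))
  rec <- fitness_records(
    genotype_id = ids,
    w_start = vapply(founders, function(cl) cl$w, numeric(1)),
    w_final = rowMeans(finals),
    generations = config$T,
    scale = "relative"
  )
  attr(rec, "replicate_finals") <- finals
  rec
}

#' Fixation probability of a single mutant by direct simulation
#'
#' Runs many replicate Wright-Fisher populations of two genotype classes
#' (one initial copy of a mutant of relative fitness \eqn{1+s} among
#' \eqn{N-1} residents of fitness 1, no further mutation) to absorption,
#' and returns the fraction of replicates in which the mutant fixed.
#' For two classes the multinomial resampling of [selection_step()]
#' reduces to a binomial draw, which lets all replicates advance in one
#' vectorized step per generation; the dynamics are identical.
#'
#' The diffusion approximation for comparison is Kimura's
#' \eqn{(1 - e^{-2s}) / (1 - e^{-2Ns})} (with the neutral limit
#' \eqn{1/N}).
#'
#' @param N population size.
#' @param s selection coefficient of the mutant (0 for neutral).
#' @param reps number of replicate populations.
#' @param seed RNG seed.
#' @param max_gen safety cap on generations (absorption is certain; the
#'   default is far beyond the absorption-time tail).
#' @return A list with \code{fixed} (count), \code{reps},
#'   \code{p_hat}, \code{se} (binomial standard error), and
#'   \code{p_kimura}.
#' @export
fixation_probability <- function(N, s, reps, seed, max_gen = 1000 * N) {
  set.seed(seed)
  cnt <- rep.int(1L, reps)        # mutant copies per replicate
  fixed <- 0L
  gen <- 0L
  while (length(cnt) && gen < max_gen) {
    p <- cnt * (1 + s) / (cnt * (1 + s) + (N - cnt))
    cnt <- stats::rbinom(length(cnt), N, p)
    fixed <- fixed + sum(cnt == N)
    cnt <- cnt[cnt > 0L & cnt < N]
    gen <- gen + 1L
  }
  if (length(cnt))
    warning(length(cnt), " replicates unresolved at max_gen")
  p_hat <- fixed / reps
  list(fixed = fixed, reps = reps, p_hat = p_hat,
       se = sqrt(p_hat * (1 - p_hat) / reps),
       p_kimura = kimura_fixation(N, s))
}

#' @rdname fixation_probability
#' @export
kimura_fixation <- function(N, s) {
  if (s == 0) return(1 / N)
  (1 - exp(-2 * s)) / (1 - exp(-2 * N * s))
}
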