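#' Macroscopic-epistasis model specifications
#'
#' Four models of how the supply of beneficial mutations changes with the
#' current fitness \eqn{w} of a genetic background ("macroscopic"
#' epistasis).  Each constructor returns a \code{model_spec} object used
#' by the simulator to decide, per individual and per generation, the
#' beneficial mutation rate and the fitness of a mutant.
#'
#' \describe{
#'   \item{\code{model_diminishing_effects}}{constant mutation rate
#'     \code{mu}; beneficial selection coefficients
#'     \eqn{s \sim Exp(\alpha_w)} with \eqn{\alpha_w = \alpha_0 w^g}, so
#'     the mean effect \eqn{1/\alpha_w} shrinks as fitness rises.}
#'   \item{\code{model_declining_rate}}{constant effect distribution
#'     \eqn{s \sim Exp(\alpha)} but a fitness-dependent rate
#'     \eqn{\mu_w = \mu_0 w^{-g}}: fitter backgrounds mutate
#'     beneficially less often.}
#'   \item{\code{model_finite_sites}}{\code{L} beneficial sites whose
#'     effects \eqn{s_j \sim Exp(\alpha)} are drawn once per model
#'     instance and fixed; each mutation irreversibly flips a uniformly
#'     chosen unmutated site, multiplying fitness by \eqn{1+s_j}.  The
#'     supply depletes: once every site is mutated, further mutation is a
#'     no-op.  This is the only model with no microscopic epistasis.}
#'   \item{\code{model_fgm}}{Fisher's geometric model: a phenotype is a
#'     point \eqn{z} in \eqn{n}-dimensional trait space with a single
#'     optimum at the origin and Gaussian fitness
#'     \eqn{w(z) = e^{-\|z\|^2/2}}.  Mutations displace the phenotype by
#'     an isotropic normal step (sd \code{sigma} per axis) and may be
#'     beneficial or deleterious.}
#' }
#'
#' In models A-C, effects compose multiplicatively:
#' child \eqn{w = w_{parent} (1+s)} with \eqn{s > 0} (beneficial-only
#' supply).  FGM fitness is bounded by 1 and mutations are unfiltered.
#' Default shape parameters keep typical effect sizes in the 1-10 percent
#' range observed experimentally; they are working defaults, not
#' estimates from any particular study.
#'
#' @param mu,mu0 per-individual beneficial mutation rate (baseline for
#'   \code{model_declining_rate}); must lie in (0, 1].
#' @param alpha0,alpha exponential rate of the beneficial-effect
#'   distribution (baseline for \code{model_diminishing_effects}); mean
#'   effect is its inverse.
#' @param g non-negative fitness-coupling exponent.
#' @param L number of beneficial sites.
#' @param site_effects optional length-\code{L} vector of positive
#'   per-site effects; if \code{NULL} they are drawn
#'   \eqn{Exp(\alpha)} at construction (seed the RNG for
#'   reproducibility).
#' @param n phenotypic dimensionality.
#' @param sigma per-axis mutation-step standard deviation.
#' @param decay fitness-decay form; only \code{"gaussian"} is
#'   implemented.
#' @return A \code{model_spec} object.
#' @name model_spec
NULL

new_model_spec <- function(kind, params) {
  structure(list(kind = kind, params = params), class = "model_spec")
}

check_rate_param <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0 || x > 1)
    stop(name, " must be a single value in [0, 1]")
  x
}

check_pos_param <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
    stop(name, " must be a single positive value")
  x
}

#' @rdname model_spec
#' @export
model_diminishing_effects <- function(mu = 1e-5, alpha0 = 20, g = 1) {
  check_rate_param(mu, "mu")
  check_pos_param(alpha0, "alpha0")
  if (g < 0) stop("g must be >= 0")
  new_model_spec("diminishing_effects",
                 list(mu = mu, alpha0 = alpha0, g = g))
}

#' @rdname model_spec
#' @export
model_declining_rate <- function(mu0 = 1e-5, alpha = 20, g = 1) {
  check_rate_param(mu0, "mu0")
  check_pos_param(alpha, "alpha")
  if (g < 0) stop("g must be >= 0")
  new_model_spec("declining_rate", list(mu0 = mu0, alpha = alpha, g = g))
}

#' @rdname model_spec
#' @export
model_finite_sites <- function(mu = 1e-5, L = 100, alpha = 20,
                               site_effects = NULL) {
  check_rate_param(mu, "mu")
  check_pos_param(alpha, "alpha")
  L <- as.integer(L)
  if (is.na(L) || L < 1) stop("L must be a positive integer")
  if (is.null(site_effects)) site_effects <- stats::rexp(L, rate = alpha)
  if (length(site_effects) != L || any(site_effects <= 0))
    stop("site_effects must be length L and positive")
  new_model_spec("finite_sites",
                 list(mu = mu, L = L, alpha = alpha,
                      site_effects = as.numeric(site_effects)))
}

#' @rdname model_spec
#' @export
model_fgm <- function(mu = 1e-5, n = 10, sigma = 0.05,
                      decay = "gaussian") {
  check_rate_param(mu, "mu")
  check_pos_param(sigma, "sigma")
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("n must be a positive integer")
  decay <- match.arg(decay, "gaussian")
  new_model_spec("fgm", list(mu = mu, n = n, sigma = sigma, decay = decay))
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$kind, "\n")
  p <- x$params
  p$site_effects <- NULL
  cat(" ", paste(names(p), unlist(p), sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' FGM fitness of a phenotype
#'
#' Gaussian fitness decay from a single optimum at the origin:
#' \eqn{w(z) = e^{-\|z\|^2/2}}, so \eqn{w(0) = 1} and
#' \eqn{w \in (0, 1]}.
#'
#' @param z numeric phenotype vector, or a matrix with one phenotype per
#'   row.
#' @return Fitness value(s) in (0, 1].
#' @export
fgm_fitness <- function(z) {
  if (is.matrix(z)) exp(-rowSums(z^2) / 2) else exp(-sum(z^2) / 2)
}

#' Per-individual beneficial mutation rate under a model
#'
#' Constant at \code{mu} for the diminishing-effects, finite-sites and
#' FGM models; \eqn{\mu_w = \mu_0 w^{-g}} for the declining-rate model.
#' A computed rate above 1 is an error (reduce \code{mu0}); it is never
#' clipped.
#'
#' @param model a \code{model_spec}.
#' @param w positive fitness value(s) of the background.
#' @return Mutation rate(s) in [0, 1].
#' @export
beneficial_rate <- function(model, w) {
  stopifnot(inherits(model, "model_spec"))
  if (any(!is.finite(w)) || any(w <= 0)) stop("w must be positive")
  p <- model$params
  rate <- switch(model$kind,
    declining_rate = p$mu0 * w^(-p$g),
    rep_len(p$mu, length(w))
  )
  if (any(rate > 1))
    stop("computed mutation rate exceeds 1; reduce the baseline rate")
  rate
}

#' Genotype classes
#'
#' A genotype class is one fitness class of the population: a fitness
#' value, an abundance, and model-specific state (nothing for the
#' diminishing-effects and declining-rate models, the set of mutated
#' sites for the finite-sites model, a phenotype vector for FGM).
#'
#' @param w positive fitness.
#' @param count non-negative abundance.
#' @param state model-specific payload.
#' @return A \code{genotype_class} object.
#' @export
genotype_class <- function(w, count = 0L, state = NULL) {
  if (!is.finite(w) || w <= 0) stop("w must be positive")
  count <- as.numeric(count)
  if (!is.finite(count) || count < 0) stop("count must be non-negative")
  structure(list(w = w, count = count, state = state),
            class = "genotype_class")
}

#' Draw one mutant of a parent class
#'
#' Applies the model's mutational move to a parent genotype class and
#' returns the mutant as a new class of count 1:
#' beneficial \eqn{s \sim Exp(\alpha_w)} (diminishing effects) or
#' \eqn{Exp(\alpha)} (declining rate) with child
#' \eqn{w = w_{parent}(1+s)}; a uniformly chosen unmutated site for the
#' finite-sites model (a no-op if all sites are mutated); an isotropic
#' normal phenotype displacement for FGM.
#'
#' @param model a \code{model_spec}.
#' @param parent a \code{genotype_class} valid under the model (for the
#'   finite-sites model, \code{state} is an integer vector of mutated
#'   site indices; for FGM, the phenotype vector).
#' @return A \code{genotype_class} of count 1.
#' @export
draw_mutant <- function(model, parent) {
  stopifnot(inherits(model, "model_spec"),
            inherits(parent, "genotype_class"))
  p <- model$params
  switch(model$kind,
    diminishing_effects = {
      s <- stats::rexp(1, rate = p$alpha0 * parent$w^p$g)
      genotype_class(parent$w * (1 + s), 1L)
    },
    declining_rate = {
      s <- stats::rexp(1, rate = p$alpha)
      genotype_class(parent$w * (1 + s), 1L)
    },
    finite_sites = {
      mutated <- parent$state
      if (!is.null(mutated) && !is.numeric(mutated))
        stop("finite_sites parent state must be an integer site vector")
      free <- setdiff(seq_len(p$L), mutated)
      if (length(free) == 0)
        return(genotype_class(parent$w, 1L, state = parent$state))
      j <- if (length(free) == 1) free else sample(free, 1)
      genotype_class(parent$w * (1 + p$site_effects[j]), 1L,
                     state = c(mutated, j))
    },
    fgm = {
      z <- parent$state
      if (!is.numeric(z) || length(z) != p$n)
        stop("fgm parent state must be a length-n phenotype vector")
      z2 <- z + stats::rnorm(p$n, sd = p$sigma)
      genotype_class(fgm_fitness(z2), 1L, state = z2)
    }
  )
}

#' Construct a founder class at a target fitness
#'
#' Builds a monomorphic founder for a simulation run.  For the
#' diminishing-effects, declining-rate and finite-sites models the
#' fitness is assigned directly with fresh (empty) state; for FGM the
#' founder phenotype is placed at distance \eqn{d = \sqrt{-2\ln w_0}}
#' from the optimum along the first axis, so that \eqn{w(z) = w_0}
#' exactly (requires \eqn{w_0 \le 1}).
#'
#' Note that for the finite-sites model this founder has its full
#' mutational supply regardless of \code{w0}; to build a fitness ladder
#' whose fitter rungs have correspondingly depleted supply, use
#' [founder_ladder()].
#'
#' @param model a \code{model_spec}.
#' @param w0 target fitness; for FGM must be in (0, 1].
#' @param count founder abundance (usually the population size).
#' @return A \code{genotype_class}.
#' @export
founder_at_fitness <- function(model, w0, count = 0L) {
  stopifnot(inherits(model, "model_spec"))
  if (!is.finite(w0) || w0 <= 0) stop("w0 must be positive")
  if (model$kind == "fgm") {
    if (w0 > 1) stop("FGM fitness cannot exceed 1 (optimum fitness)")
    d <- sqrt(-2 * log(w0))
    z <- c(d, rep(0, model$params$n - 1))
    genotype_class(fgm_fitness(z), count, state = z)
  } else if (model$kind == "finite_sites") {
    genotype_class(w0, count, state = integer(0))
  } else {
    genotype_class(w0, count)
  }
}

#' Build a ladder of founders spanning a fitness range
#'
#' Produces founders whose initial fitness values climb from the least
#' to the most fit, for use with [run_experiment()].  Targets are
#' expressed as per-generation log-fitness deficits \eqn{|x|} below the
#' top of the ladder over a horizon of \code{generations}, matching the
#' standardized x-axis of the analysis: founder \eqn{i} aims at
#' \eqn{w_i = w_{top} e^{-|x_i| G}}.
#'
#' For the diminishing-effects, declining-rate and FGM models the target
#' fitness is hit exactly via [founder_at_fitness()] (FGM founders are
#' placed at the corresponding distance from the optimum, so
#' \code{w_top} must be at most 1).  For the finite-sites model a fitter
#' founder must also carry a more depleted supply of beneficial sites --
#' in that model fitness *is* the record of sites already exploited --
#' so the ladder starts from the all-sites-available base genotype
#' (fitness \code{w_top} divided by the full ladder span) and mutates
#' sites in decreasing order of effect until each target is reached or
#' passed, mirroring the substitution order adaptation itself favours
#' (strong sites first); the realised fitness (not the target) is
#' stored on the class.
#'
#' @param model a \code{model_spec}.
#' @param deficits vector of non-negative per-generation log deficits,
#'   one per founder; 0 is the top of the ladder.
#' @param generations horizon over which deficits are expressed.
#' @param w_top fitness at the top of the ladder (deficit 0).
#' @param count abundance given to every founder.
#' @return A list of \code{genotype_class} founders, ordered as
#'   \code{deficits}.
#' @export
founder_ladder <- function(model, deficits, generations, w_top = 1,
                           count = 0L) {
  stopifnot(inherits(model, "model_spec"))
  if (any(deficits < 0)) stop("deficits must be non-negative")
  targets <- w_top * exp(-deficits * generations)
  if (model$kind != "finite_sites")
    return(lapply(targets, founder_at_fitness, model = model,
                  count = count))
  # finite sites: climb from the base genotype by pre-mutating the
  # strongest sites first
  p <- model$params
  w_base <- min(targets)
  order_sites <- order(p$site_effects, decreasing = TRUE)
  founders <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    w <- w_base
    k <- 0L
    while (w < targets[i] && k < p$L) {
      k <- k + 1L
      w <- w * (1 + p$site_effects[order_sites[k]])
    }
    founders[[i]] <- genotype_class(w, count,
                                    state = sort(order_sites[seq_len(k)]))
  }
  founders
}
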