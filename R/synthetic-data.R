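#' Generate a synthetic fitness-record collection
#'
#' Draws a collection of genotypes with graded initial fitness deficits
#' and excess gains following a known power law, then converts the
#' coordinates back into initial/final fitness values — the exact
#' inverse of [standardize()] followed by the log-log model, so the
#' pipeline can be exercised and calibrated without any external data.
#'
#' Per-generation deficit magnitudes \eqn{|x_i|} are drawn uniformly on
#' \code{deficit_range}, with one genotype pinned at deficit 0 as the
#' reference (fittest founder).  Expected excess gains follow
#' \deqn{E[y_i] = gain\_scale \cdot |x_i|^{\beta}}
#' and measurement noise is lognormal: \eqn{\ln y_i} receives additive
#' Gaussian noise of sd \code{noise_sd}, the conventional error model
#' for relative-fitness assays (noise on the log-fitness scale).  The
#' reference genotype's own per-generation gain is fixed at
#' \code{ref_gain}.  With \code{noise_sd = 0},
#' \code{standardize(generate_collection(...))} recovers the generating
#' \eqn{(x, y)} exactly and [fit_loglog()] recovers \code{true_beta} to
#' numerical precision.
#'
#' @param n_genotypes number of genotypes including the reference
#'   (>= 2).
#' @param deficit_range length-2 vector (min, max) of per-generation
#'   log-deficit magnitudes, max >= min >= 0 (the degenerate
#'   \code{c(0, 0)} puts every genotype at the reference fitness).
#' @param true_beta generating log-log slope (> 0).
#' @param gain_scale prefactor of the power law, in per-generation
#'   log-fitness units.
#' @param noise_sd standard deviation of the Gaussian noise on
#'   \eqn{\ln y} (>= 0).
#' @param generations elapsed generations used in the back-conversion.
#' @param seed RNG seed (required).
#' @param ref_gain per-generation log-gain of the reference genotype.
#' @param w_ref_start initial fitness of the reference genotype.
#' @return A \code{fitness_records} data frame; the generating
#'   coordinates are attached as attribute \code{"truth"}.
#' @export
#' @examples
#' rec <- generate_collection(16, c(5e-4, 5e-3), true_beta = 0.8,
#'                            generations = 500, seed = 1)
#' fit_loglog(standardize(rec))$beta
generate_collection <- function(n_genotypes, deficit_range, true_beta,
                                gain_scale = 1, noise_sd = 0,
                                generations = 500, seed,
                                ref_gain = 1e-3, w_ref_start = 1) {
  if (missing(seed)) stop("an RNG seed is required")
  if (n_genotypes < 2) stop("n_genotypes must be >= 2")
  if (true_beta <= 0) stop("true_beta must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(deficit_range) != 2 || diff(deficit_range) < 0 ||
      deficit_range[1] < 0)
    stop("deficit_range must be (min, max) with max >= min >= 0")
  set.seed(seed)
  dx <- c(0, stats::runif(n_genotypes - 1, deficit_range[1],
                          deficit_range[2]))
  y <- gain_scale * dx^true_beta
  if (noise_sd > 0) {
    eps <- stats::rnorm(n_genotypes, sd = noise_sd)
    y[-1] <- y[-1] * exp(eps[-1])
  }
  y[1] <- 0                                   # reference by construction
  G <- generations
  w_start <- w_ref_start * exp(-dx * G)
  w_final <- w_start * exp((y + ref_gain) * G)
  ids <- c("reference",
           sprintf("g%03d", seq_len(n_genotypes - 1)))
  rec <- fitness_records(ids, w_start, w_final, G, scale = "relative")
  attr(rec, "truth") <- data.frame(genotype_id = ids, x = -dx, y = y)
  rec
}

#' Study-design presets for the synthetic generator
#'
#' Structural mimics of the designs of five published
#' evolve-and-compare experiments: the number of founder genotypes and
#' the generations of evolution match the studies, while deficit ranges,
#' noise levels and the generating slope are documented working values
#' (the studies' actual fitness tables are not reproduced).
#'
#' \tabular{lllll}{
#' preset \tab genotypes \tab generations \tab emulates \cr
#' \code{yeastdel187} \tab 187 \tab 400 \tab yeast single-gene deletion
#'   mutants with graded growth defects (noisy; loss-of-function
#'   lesions) \cr
#' \code{ydiv64_250} \tab 64 \tab 250 \tab yeast lines adaptively
#'   diverged from one ancestor, first timepoint \cr
#' \code{ydiv64_500} \tab 64 \tab 500 \tab the same lines at the second
#'   timepoint (shallower slope) \cr
#' \code{rif8} \tab 8 \tab 500 \tab costly rifampicin-resistant
#'   point mutants of E. coli \cr
#' \code{hyper23} \tab 23 \tab 640 \tab bottlenecked hypermutator
#'   lineages (steepest slope, noisy) \cr
#' \code{phage8} \tab 8 \tab 240 \tab microvirid phage strains of
#'   diverse infection efficiency \cr
#' }
#'
#' @return \code{study_presets()} returns the preset table as a data
#'   frame.
#' @export
study_presets <- function() {
  data.frame(
    name = c("yeastdel187", "ydiv64_250", "ydiv64_500", "rif8",
             "hyper23", "phage8"),
    n_genotypes = c(187L, 64L, 64L, 8L, 23L, 8L),
    generations = c(400L, 250L, 500L, 500L, 640L, 240L),
    deficit_min = c(2e-4, 1e-4, 5e-5, 5e-4, 2e-4, 5e-4),
    deficit_max = c(5e-3, 2e-3, 1e-3, 5e-3, 5e-3, 5e-3),
    noise_sd = c(0.45, 0.25, 0.25, 0.15, 0.40, 0.15),
    true_beta = c(0.8, 0.8, 0.9, 0.85, 1.1, 0.85),
    stringsAsFactors = FALSE
  )
}

#' Generate a collection shaped like one of the study designs
#'
#' @param preset_name one of the names in [study_presets()].
#' @param true_beta generating slope; defaults to the preset's value.
#' @param seed RNG seed (required).
#' @return A \code{fitness_records} data frame; see
#'   [generate_collection()].
#' @export
#' @examples
#' nrow(emulate_study("rif8", seed = 1))   # 8
emulate_study <- function(preset_name, true_beta = NULL, seed) {
  if (missing(seed)) stop("an RNG seed is required")
  presets <- study_presets()
  i <- match(preset_name, presets$name)
  if (is.na(i))
    stop("unknown preset '", preset_name, "'; see study_presets()")
  p <- presets[i, ]
  generate_collection(
    n_genotypes = p$n_genotypes,
    deficit_range = c(p$deficit_min, p$deficit_max),
    true_beta = if (is.null(true_beta)) p$true_beta else true_beta,
    noise_sd = p$noise_sd,
    generations = p$generations,
    seed = seed
  )
}
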