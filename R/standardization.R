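#' Fitness records
#'
#' A fitness record holds one genotype's initial and final fitness, the
#' number of generations of evolution between the two measurements, and a
#' tag declaring the scale on which fitness was measured.  Collections of
#' records are plain data frames so they can be filtered and joined with
#' ordinary tools.
#'
#' Supported scales:
#' \describe{
#'   \item{\code{relative}}{per-generation relative fitness, i.e. a
#'     per-generation multiplier whose natural log is a Malthusian
#'     difference.}
#'   \item{\code{growth_rate_ratio}}{a ratio of growth rates accumulated
#'     over a multi-generation assay; converted to a per-generation
#'     multiplier by taking the \code{assay_generations}-th root.}
#'   \item{\code{malthusian_exp}}{fitness already expressed as
#'     \eqn{e^m} for a per-generation Malthusian difference \eqn{m};
#'     passed through unchanged.}
#' }
#'
#' @param genotype_id character vector of genotype labels (unique).
#' @param w_start,w_final positive numeric vectors of initial and final
#'   fitness on the declared scale.
#' @param generations positive integer vector (recycled) of elapsed
#'   generations of evolution.
#' @param scale scale tag, one of \code{"relative"},
#'   \code{"growth_rate_ratio"}, \code{"malthusian_exp"} (recycled).
#' @return A data frame of class \code{fitness_records} with columns
#'   \code{genotype_id}, \code{w_start}, \code{w_final},
#'   \code{generations}, \code{scale}.
#' @export
#' @examples
#' fitness_records(c("wt", "mutA"), c(1.0, 0.9), c(1.05, 1.02), 500)
fitness_records <- function(genotype_id, w_start, w_final, generations,
                            scale = "relative") {
  genotype_id <- as.character(genotype_id)
  if (anyDuplicated(genotype_id)) stop("genotype_id values must be unique")
  if (any(!is.finite(w_start)) || any(w_start <= 0))
    stop("w_start must be positive and finite")
  if (any(!is.finite(w_final)) || any(w_final <= 0))
    stop("w_final must be positive and finite")
  generations <- as.integer(generations)
  if (any(is.na(generations)) || any(generations < 1))
    stop("generations must be a positive integer")
  scale <- match_scale(scale)
  out <- data.frame(
    genotype_id = genotype_id,
    w_start = as.numeric(w_start),
    w_final = as.numeric(w_final),
    generations = rep_len(generations, length(genotype_id)),
    scale = rep_len(scale, length(genotype_id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("fitness_records", "data.frame")
  out
}

fitness_scales <- c("relative", "growth_rate_ratio", "malthusian_exp")

match_scale <- function(scale) {
  scale <- as.character(scale)
  bad <- setdiff(unique(scale), fitness_scales)
  if (length(bad))
    stop("unknown fitness scale: ", paste(bad, collapse = ", "))
  scale
}

#' Convert a fitness value to the common Malthusian (multiplier) scale
#'
#' All downstream analysis works with per-generation multipliers
#' \eqn{e^m}, where \eqn{m} is a Malthusian-parameter difference per
#' generation.  Relative-fitness and \code{malthusian_exp} inputs are
#' already on that scale; growth-rate ratios measured over a
#' multi-generation assay are converted by taking the per-generation
#' root.
#'
#' @param value positive fitness value(s) on the declared scale.
#' @param scale scale tag; see [fitness_records()].
#' @param assay_generations number of generations spanned by the assay
#'   (used only for \code{growth_rate_ratio}); must be positive.
#' @return Fitness as a per-generation multiplier; its natural log is a
#'   Malthusian difference per generation.
#' @export
#' @examples
#' to_malthusian(4, "growth_rate_ratio", assay_generations = 2)  # 2
to_malthusian <- function(value, scale, assay_generations = 1) {
  if (any(!is.finite(value)) || any(value <= 0))
    stop("fitness value must be positive and finite")
  if (!is.numeric(assay_generations) || length(assay_generations) != 1 ||
      !is.finite(assay_generations) || assay_generations <= 0)
    stop("assay_generations must be a single positive number")
  scale <- match_scale(scale)
  scale <- rep_len(scale, length(value))
  out <- value
  grr <- scale == "growth_rate_ratio"
  if (any(grr)) out[grr] <- value[grr]^(1 / assay_generations)
  out
}

#' Identify the fittest founder of a collection
#'
#' Returns the genotype with maximal initial fitness; ties are broken
#' deterministically toward the lexicographically smallest
#' \code{genotype_id}.
#'
#' @param records a \code{fitness_records} data frame.
#' @return The \code{genotype_id} of the reference genotype.
#' @export
select_reference <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("records must be a non-empty fitness_records data frame")
  top <- records$genotype_id[records$w_start == max(records$w_start)]
  sort(top, method = "radix")[1]
}

#' Standardize fitness records against the fittest founder
#'
#' Converts a collection of fitness records into the per-generation
#' coordinates on which declining adaptability is assessed.  With
#' reference genotype \eqn{r} (the fittest founder) and per-record
#' generation count \eqn{G}:
#' \deqn{x_i = \ln(w_{i,start}/w_{r,start}) / G}
#' \deqn{y_i = [\ln(w_{i,final}/w_{i,start}) -
#'              \ln(w_{r,final}/w_{r,start})] / G}
#' so \eqn{x_i \le 0} is the initial log-fitness deficit per generation
#' and \eqn{y_i} the excess log-fitness gain per generation, both in
#' natural-log units.  The reference maps to \eqn{(0, 0)} by
#' construction, and both coordinates are invariant under rescaling all
#' fitness values by one positive constant.
#'
#' All fitness values are first brought onto the Malthusian multiplier
#' scale with [to_malthusian()] according to each record's declared
#' scale.
#'
#' @param records a \code{fitness_records} data frame.
#' @param generations optional single generation count overriding the
#'   per-record values (collections mixing experiments of different
#'   lengths keep their per-record counts by default).
#' @param assay_generations assay span passed to [to_malthusian()] for
#'   \code{growth_rate_ratio} records.
#' @param x_from which initial fitness enters the deficit coordinate.
#'   The default \code{"start"} uses \eqn{w_{i,start}}, which anchors the
#'   reference at the origin; \code{"final"} is exposed for comparison
#'   only and uses \eqn{w_{i,final}} in the numerator of \eqn{x}.
#' @return A data frame of class \code{standardized_points} with columns
#'   \code{genotype_id}, \code{x}, \code{y}, \code{reference_flag}.
#' @export
#' @examples
#' rec <- fitness_records(c("ref", "a"), c(1, exp(-0.1)),
#'                        c(exp(0.1), exp(-0.1 + 0.2)), 100)
#' standardize(rec)
standardize <- function(records, generations = NULL,
                        assay_generations = 1,
                        x_from = c("start", "final")) {
  x_from <- match.arg(x_from)
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("records must be a non-empty fitness_records data frame")
  G <- if (is.null(generations)) records$generations else
    rep_len(generations, nrow(records))
  if (any(!is.finite(G)) || any(G <= 0))
    stop("generation counts must be positive")
  ws <- to_malthusian(records$w_start, records$scale, assay_generations)
  wf <- to_malthusian(records$w_final, records$scale, assay_generations)
  ref <- select_reference(records)
  i_ref <- match(ref, records$genotype_id)
  x_num <- if (x_from == "start") ws else wf
  x <- (log(x_num) - log(ws[i_ref])) / G
  y <- ((log(wf) - log(ws)) - (log(wf[i_ref]) - log(ws[i_ref]))) / G
  out <- data.frame(
    genotype_id = records$genotype_id,
    x = x, y = y,
    reference_flag = records$genotype_id == ref,
    stringsAsFactors = FALSE
  )
  class(out) <- c("standardized_points", "data.frame")
  out
}

#' Read and write fitness-record and standardized-point tables
#'
#' Tab- or comma-separated tables with a header row; lines starting with
#' \code{#} are comments.  Fitness tables require the columns
#' \code{genotype_id}, \code{w_start}, \code{w_final},
#' \code{generations}, \code{scale}.
#'
#' @param path file path.
#' @param records,points objects to write.
#' @return \code{read_fitness_records} returns a \code{fitness_records}
#'   data frame; the writers return their input invisibly.
#' @export
read_fitness_records <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "",
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("genotype_id", "w_start", "w_final", "generations", "scale")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "))
  fitness_records(tab$genotype_id, tab$w_start, tab$w_final,
                  tab$generations, tab$scale)
}

#' @rdname read_fitness_records
#' @export
write_fitness_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(records)
}

#' @rdname read_fitness_records
#' @export
write_standardized <- function(points, path) {
  utils::write.table(points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(points)
}
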