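#' Generation scale for a serial-transfer experiment
#'
#' A serial-batch evolution experiment is propagated by daily transfers, each
#' corresponding to a fixed number of cell generations (the regrowth factor per
#' transfer). The scale converts the experiment's day axis to the generation
#' axis on which population-genetic quantities (drift variance, mutation
#' dating) are computed.
#'
#' @param gens_per_day Positive number of generations elapsed per experimental
#'   day. The default 6.7 corresponds to a 100-fold daily dilution regime
#'   (log2(100) ~ 6.64, conventionally rounded to 6.7).
#'
#' @return An object of class `generation_scale`.
#' @examples
#' sc <- generation_scale()
#' day_to_generation(156, sc)
#' @export
generation_scale <- function(gens_per_day = 6.7) {
  if (!is.numeric(gens_per_day) || length(gens_per_day) != 1 ||
      !is.finite(gens_per_day) || gens_per_day <= 0) {
    stop("`gens_per_day` must be a single positive number.", call. = FALSE)
  }
  structure(list(gens_per_day = as.numeric(gens_per_day)),
            class = "generation_scale")
}

#' @export
print.generation_scale <- function(x, ...) {
  cat("<generation_scale> ", x$gens_per_day, " generations per day\n", sep = "")
  invisible(x)
}

#' Convert experiment days to generations
#'
#' Converts a day of the experiment to the elapsed number of whole generations,
#' `floor(day * gens_per_day)`. With the default scale of 6.7 generations per
#' day, day 156 (the clone-extraction day) maps to generation 1045 and day 72
#' to generation 482.
#'
#' @param day Vector of non-negative integer days.
#' @param scale A [generation_scale()] object.
#'
#' @return Integer vector of generations, same length as `day`.
#' @examples
#' day_to_generation(c(0, 72, 156, 183))
#' @export
day_to_generation <- function(day, scale = generation_scale()) {
  if (!inherits(scale, "generation_scale")) scale <- generation_scale(scale)
  if (!is.numeric(day) || any(!is.finite(day)) || any(day < 0)) {
    stop("`day` must be non-negative and finite.", call. = FALSE)
  }
  as.integer(floor(day * scale$gens_per_day))
}
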