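# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate code under a given RNG seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# reproducible child-seed derivation (documented fan-out: one master seed per
# run, one derived seed per stage/subject); kept below 2^31 - 1
derive_seed <- function(seed, k) {
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + 104729 * (as.numeric(k) %% 10007)) %% 2147483647)
}

#' Integer percentage with halves rounded away from zero
#'
#' The rounding convention used for every frequency table: `percent =
#' round(100 * count / n)` with exact halves rounded away from zero, returned
#' as an integer (e.g. 17 of 30 knees -> 57, 19 of 30 -> 63, 28 of 30 -> 93).
#'
#' @param count Non-negative integer count(s).
#' @param n Denominator (number of knees).
#' @return Integer vector of percentages.
#' @export
percent_integer <- function(count, n) {
  stopifnot(n >= 1, all(count >= 0), all(count <= n))
  as.integer(floor(100 * count / n + 0.5))
}

# accept either a bare logical array or an ROI object
as_mask <- function(x) {
  if (inherits(x, "subchondral_roi")) x$mask
  else if (is.logical(x) || is.array(x)) {
    storage.mode(x) <- "logical"
    x
  } else stop("expected a logical mask or a subchondral_roi", call. = FALSE)
}

is_femur <- function(bone) grepl("femur", bone, fixed = TRUE)

check_bone <- function(bone) {
  bone <- match.arg(bone, c("distal_femur", "tibial_plateau", "femur", "tibia"))
  if (is_femur(bone)) "distal_femur" else "tibial_plateau"
}

check_side <- function(side) match.arg(side, c("right", "left"))
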