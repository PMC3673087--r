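`%||%` <- function(a, b) if (is.null(a)) b else a

## Signed area of a polygon given as an n x 2 matrix (shoelace formula);
## positive for counter-clockwise vertex order in (u right, v down) pixel
## coordinates as plotted, i.e. we only rely on the sign being consistent.
signedPolygonArea <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]) / 2
}

## Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
## caller's stream afterwards so seeded helpers do not perturb user code.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Round half away from zero (images are non-negative so this is half-up);
## base round() rounds half to even, which would bias integer image maths.
roundHalfUp <- function(x) floor(x + 0.5)

assertRGBImage <- function(image, arg = "image") {
  d <- dim(image)
  if (is.null(d) || length(d) != 3 || d[3] != 3)
    stop(sprintf("`%s` must be an H x W x 3 array", arg), call. = FALSE)
  invisible(d)
}

assertMask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask))
    stop(sprintf("`%s` must be a logical matrix", arg), call. = FALSE)
  invisible(dim(mask))
}
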