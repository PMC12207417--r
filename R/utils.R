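## Internal helpers shared across modules.

## Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
## state afterwards. All stochastic draws in the package flow through this.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

## Time column index (1-based) covering second t: column c covers [c-1, c).
.timeToCol <- function(t) floor(t) + 1L

## Depth row index (1-based) covering metre d: row r covers [0.5(r-1), 0.5r).
.depthToRow <- function(d) floor(d / 0.5) + 1L

## Rows covering the half-open depth interval [a, b), clamped to 1..nD.
.rowsForDepth <- function(a, b, nD) {
  r1 <- max(1L, floor(a / 0.5) + 1L)
  r2 <- min(nD, ceiling(b / 0.5))
  if (r2 < r1) integer(0) else r1:r2
}

## Columns covering the half-open time interval [a, b), clamped to 1..nT.
.colsForTime <- function(a, b, nT) {
  c1 <- max(1L, floor(a) + 1L)
  c2 <- min(nT, ceiling(b))
  if (c2 < c1) integer(0) else c1:c2
}

.isCount <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == round(x)

.assertScalarNum <- function(x, nm) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x))
    stop(nm, " must be a single non-missing number", call. = FALSE)
  invisible(x)
}
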