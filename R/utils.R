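## Internal helpers shared across modules.

## Run `expr` under a private RNG state seeded with `seed`, restoring the
## caller's .Random.seed afterwards so generators never perturb user code.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

clip01 <- function(x) pmin(1, pmax(0, x))

## "Tyr122" / "HIS236" / "arg110" -> list(resid = "TYR", resno = 122)
parseResidueLabel <- function(label) {
  if (is.numeric(label)) return(list(resid = NULL, resno = as.integer(label)))
  m <- regmatches(label, regexec("^([A-Za-z]{3})\\s*([0-9]+)$", label))[[1]]
  if (length(m) != 3L)
    stop("cannot parse residue label '", label,
         "' (expected e.g. 'Tyr122' or a residue number)", call. = FALSE)
  list(resid = toupper(m[2]), resno = as.integer(m[3]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
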