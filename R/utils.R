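# Internal helpers: classed conditions, seed isolation, 5-significant-digit keys.

.raError <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "ra_error")))
}

.parseError <- function(smiles) {
  .raError(sprintf("SMILES could not be parsed: '%s'", smiles),
           class = "ra_parse_error", smiles = smiles)
}

.fitError <- function(msg) .raError(msg, class = "ra_fit_error")

.configError <- function(msg) .raError(msg, class = "ra_config_error")

# Run expr under a fixed RNG seed without disturbing the caller's RNG stream.
.withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Canonical text key of a positive dose rounded to 5 significant digits.
# Duplicate detection compares these decimal representations, never raw
# floating-point values.
.sig5Key <- function(x) sprintf("%.4e", signif(x, 5L))

# Stable, locale-independent sort for feature strings.
.csort <- function(x) sort(x, method = "radix")
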