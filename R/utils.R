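# internal helpers shared across modules

# Canonicalize a label string: trim, upper-case, map known spellings.
# Unknown strings yield NA so callers can report the offending rows.
canonicalLabel <- function(x) {
  up <- toupper(trimws(as.character(x)))
  up[!(up %in% TIL_LABELS)] <- NA_character_
  up
}

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
# Keeps every stochastic stage independently reproducible from its own seed.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive a stage seed from a master seed; kept below 2^31 - 1.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

#' Hash a run configuration
#'
#' Serializes a configuration list to canonical YAML and returns its MD5
#' digest. The hash is embedded in pipeline outputs so any artifact can be
#' traced to the exact settings that produced it.
#'
#' @param config a named list of settings
#' @return character(1) MD5 hex digest
#' @export
configHash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config[order(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}
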