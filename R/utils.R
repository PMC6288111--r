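# Internal helpers shared across modules.

# Multiplicative lognormal noise with unit mean and a given coefficient of
# variation. cv = 0 returns exact ones so generators degrade cleanly to the
# noise-free limit.
.lnoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Format a numeric vector at 6 significant digits for report files so that
# repeated runs are byte-identical.
.fmt_signif <- function(x, digits = 6) {
  out <- formatC(signif(x, digits), format = "g", digits = digits)
  out[is.na(x)] <- "NA"
  out
}

# Write a report CSV with fixed float formatting and no row names.
.write_report_csv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]])) {
      df[[j]] <- .fmt_signif(df[[j]])
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# Condition constructors: typed errors so callers/tests can discriminate
# parse failures from ordinary input errors.
.lipid_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "lipidbridgeError")))
}

.parse_error <- function(msg) .lipid_error(msg, "lipidParseError")
.conversion_error <- function(msg) .lipid_error(msg, "lipidConversionError")
.input_error <- function(msg) .lipid_error(msg, "lipidInputError")
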