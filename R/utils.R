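# Classed conditions so callers can discriminate failure modes with
# tryCatch(..., lfa_config_error = ...) instead of matching message text.
lfa_error <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "lfa_error"), call = call))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Run expr under a fixed seed without disturbing the caller's RNG stream;
# seed = NULL means "use the current stream".
with_optional_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Stable hash of an R object for provenance records (md5 of its JSON form).
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}
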