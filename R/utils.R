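`%||%` <- function(a, b) if (is.null(a)) b else a

# Package-wide default seed: every randomised operation takes an explicit
# integer seed argument defaulting to this value.
HQ_DEFAULT_SEED <- 20190202L

.hq_log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Set or get the package log level
#'
#' Messages below the active level are suppressed. Levels, in order:
#' \code{"debug"}, \code{"info"}, \code{"warn"}, \code{"error"}.
#'
#' @param level character, one of the levels above; missing returns the
#'   current level.
#' @return the active level, invisibly when setting.
#' @export
hq_log_level <- function(level) {
  if (missing(level)) {
    return(getOption("hergqsar.log_level", "warn"))
  }
  level <- match.arg(level, names(.hq_log_levels))
  options(hergqsar.log_level = level)
  invisible(level)
}

hq_log <- function(level, ...) {
  lvl <- .hq_log_levels[[match.arg(level, names(.hq_log_levels))]]
  active <- .hq_log_levels[[hq_log_level()]]
  if (lvl >= active) {
    message(sprintf("[%s] %s", toupper(level), paste0(...)))
  }
  invisible(NULL)
}

# Deterministic 31-bit polynomial string hash (bytes, base 31). Used to map
# structural identifier strings to circular-fingerprint bit space. Memoised
# per session because neighbourhood strings repeat heavily across molecules.
.hash_cache <- new.env(parent = emptyenv(), hash = TRUE)

hq_hash <- function(s) {
  hit <- .hash_cache[[s]]
  if (!is.null(hit)) return(hit)
  b <- utf8ToInt(s)
  h <- 0
  for (x in b) h <- (h * 31 + x) %% 2147483647
  h <- as.integer(h)
  assign(s, h, envir = .hash_cache)
  h
}

# Derive a child seed from a master seed and a stage label, staying below
# 2^31 so the result is a valid R integer.
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + hq_hash(stage)) %% 2147483629)
}

stop_input <- function(...) stop(paste0(...), call. = FALSE)

as_call_factor <- function(x) {
  factor(as.character(x), levels = c("active", "inactive"))
}
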