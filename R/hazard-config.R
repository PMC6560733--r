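#' Read a cause-hazard specification from a config file
#'
#' Parses a declarative key-value text format describing the cause-specific
#' hazard models of both trial arms, one block per arm x component:
#'
#' ```
#' [I.1]
#' family = weibull
#' kappa = 0.24
#' nu = 1
#'
#' [C.1]
#' family = weibull
#' kappa = 0.4
#' nu = 1
#'
#' [I.2]
#' family = gompertz_makeham
#' kappa = 0.21
#' nu = 0.7
#' epsilon = -0.21
#' ...
#' ```
#'
#' Block headers are `[<group>.<component>]` with group `I` or `C` and
#' components numbered `1..k` without gaps; recognized keys are `family`,
#' `kappa`, `nu`, `epsilon`. Blank lines and lines starting with `#` are
#' ignored.
#'
#' @param file Path to the config file (or a connection).
#' @return A [cause_hazard_set()].
#' @export
read_hazard_config <- function(file) {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  blocks <- list()
  current <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      current <- sub("^\\[(.+)\\]$", "\\1", ln)
      if (!grepl("^[IC]\\.[0-9]+$", current)) {
        stop("malformed block header '[", current,
             "]'; expected [I.<j>] or [C.<j>]", call. = FALSE)
      }
      blocks[[current]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(current)) {
        stop("key-value line before any block header: '", ln, "'",
             call. = FALSE)
      }
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      if (!key %in% c("family", "kappa", "nu", "epsilon")) {
        stop("unknown key '", key, "' in block [", current, "]",
             call. = FALSE)
      }
      val <- trimws(paste(kv[-1], collapse = "="))
      blocks[[current]][[key]] <- val
    } else {
      stop("unparseable line: '", ln, "'", call. = FALSE)
    }
  }
  comp <- as.integer(sub("^[IC]\\.", "", names(blocks)))
  k <- max(comp)
  need <- c(paste0("I.", seq_len(k)), paste0("C.", seq_len(k)))
  missing <- setdiff(need, names(blocks))
  if (length(missing)) {
    stop("missing block(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  build <- function(b, name) {
    if (is.null(b$family) || is.null(b$kappa)) {
      stop("block [", name, "] needs at least 'family' and 'kappa'",
           call. = FALSE)
    }
    hazard_model(b$family,
                 kappa = as.numeric(b$kappa),
                 nu = if (is.null(b$nu)) 1 else as.numeric(b$nu),
                 epsilon = if (is.null(b$epsilon)) 0 else
                   as.numeric(b$epsilon))
  }
  cause_hazard_set(
    intervention = lapply(seq_len(k), function(j) {
      build(blocks[[paste0("I.", j)]], paste0("I.", j))
    }),
    control = lapply(seq_len(k), function(j) {
      build(blocks[[paste0("C.", j)]], paste0("C.", j))
    }))
}
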