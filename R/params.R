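#' Uncertain model parameter
#'
#' A scalar model input with its point estimate, plausible range and the
#' distribution family used for probabilistic sensitivity analysis:
#' gamma for costs, beta for probabilities and utilities, log-normal for
#' survival scale/shape parameters (centred on the log estimate with the
#' delta-method log-scale SE), or fixed.
#'
#' @param mean Point estimate used in the base case.
#' @param low,high Range for one-way sensitivity analysis (and, via the
#'   95%-interval rule `se = (high - low)/3.92`, the PSA spread).
#' @param dist `"gamma"`, `"beta"`, `"lognormal"` or `"fixed"`.
#' @param se Standard error; required for `"lognormal"`, derived from the
#'   range otherwise.
#' @return An object of class `cea_param`.
#' @export
cea_param <- function(mean, low = NA_real_, high = NA_real_,
                      dist = c("fixed", "gamma", "beta", "lognormal"),
                      se = NA_real_) {
  dist <- match.arg(dist)
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean))
  if (!is.na(low) && !is.na(high) && !(low <= mean && mean <= high))
    stop("need low <= mean <= high")
  if (dist == "beta" && (mean <= 0 || mean >= 1))
    stop("beta parameters must have mean in (0, 1)")
  if (dist == "lognormal" && is.na(se))
    stop("lognormal parameters need an `se`")
  structure(list(mean = mean, low = low, high = high, dist = dist, se = se),
            class = "cea_param")
}

#' Symmetric default range for a parameter
#'
#' The +/-20% rule applied when no empirical range is available.
#'
#' @param base Finite base value.
#' @return `c(low, high) = c(0.8, 1.2) * base` (ordered).
#' @export
default_range <- function(base) {
  stopifnot(is.numeric(base), is.finite(base))
  sort(c(0.8, 1.2) * base)
}

# shorthand constructors used by the fixture
.p_cost <- function(mean, low = NA, high = NA) {
  if (is.na(low)) { r <- default_range(mean); low <- r[1]; high <- r[2] }
  cea_param(mean, low, high, "gamma")
}
.p_prob <- function(mean, low = NA, high = NA) {
  if (is.na(low)) {
    r <- default_range(mean)
    low <- r[1]; high <- min(r[2], 1)
  }
  cea_param(mean, low, high, "beta")
}

#' Enumerate the uncertain parameters of a model specification
#'
#' Walks the nested specification and returns one row per `cea_param`
#' leaf, named by its dotted path (e.g. `arms.GP.induction.gemcitabine`).
#'
#' @param spec A model specification such as [npc_model_spec()].
#' @return A data frame with columns `name`, `mean`, `low`, `high`,
#'   `dist`, `se`.
#' @export
param_table <- function(spec) {
  rows <- list()
  walk <- function(x, path) {
    if (inherits(x, "cea_param")) {
      rows[[length(rows) + 1L]] <<- data.frame(
        name = paste(path, collapse = "."),
        mean = x$mean, low = x$low, high = x$high,
        dist = x$dist, se = x$se, stringsAsFactors = FALSE)
    } else if (is.list(x) && !inherits(x, "model_config")) {
      for (nm in names(x)) walk(x[[nm]], c(path, nm))
    }
  }
  walk(spec, character(0))
  do.call(rbind, rows)
}

# fetch / replace the mean of the cea_param at a dotted path
.get_param <- function(spec, name) {
  node <- spec
  for (key in strsplit(name, ".", fixed = TRUE)[[1]]) {
    node <- node[[key]]
    if (is.null(node)) stop("unknown parameter: ", name)
  }
  if (!inherits(node, "cea_param")) stop("not a parameter: ", name)
  node
}

set_param <- function(spec, name, value) {
  keys <- strsplit(name, ".", fixed = TRUE)[[1]]
  expr <- Reduce(function(acc, k) call("[[", acc, k), keys, quote(spec))
  target <- eval(expr, list(spec = spec))
  if (!inherits(target, "cea_param")) stop("not a parameter: ", name)
  eval(call("<-", call("$", expr, quote(mean)), value))
  spec
}

#' Look up a parameter's base-case value
#'
#' @param spec Model specification.
#' @param name Dotted parameter path.
#' @return The parameter's mean.
#' @export
param_value <- function(spec, name) .get_param(spec, name)$mean
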