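# Canonical SELU constants (self-normalising networks).
.seluLambda <- 1.0507009873554804934193349852946
.seluAlpha  <- 1.6732632423543772848170429916717

# numerically safe softplus: log(1 + e^x) -> x for large x
.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# Built-in scalar nonlinearities with closed-form derivatives. GELU uses the
# exact-erf form (x * Phi(x)), not the tanh approximation. ELU alpha = 1.
.afRegistry <- list(
  ReLU = list(
    f = function(x) pmax(x, 0),
    g = function(x) as.numeric(x > 0),
    parameters = list()),
  ELU = list(
    f = function(x) ifelse(x >= 0, x, expm1(x)),
    g = function(x) ifelse(x >= 0, 1, exp(x)),
    parameters = list(alpha = 1)),
  SELU = list(
    f = function(x) .seluLambda * ifelse(x >= 0, x, .seluAlpha * expm1(x)),
    g = function(x) .seluLambda * ifelse(x >= 0, 1, .seluAlpha * exp(x)),
    parameters = list(lambda = .seluLambda, alpha = .seluAlpha)),
  Mish = list(
    f = function(x) x * tanh(.softplus(x)),
    g = function(x) {
      t <- tanh(.softplus(x))
      t + x * (1 - t^2) * stats::plogis(x)
    },
    parameters = list()),
  SiLU = list(
    f = function(x) x * stats::plogis(x),
    g = function(x) {
      s <- stats::plogis(x)
      s * (1 + x * (1 - s))
    },
    parameters = list()),
  GELU = list(
    f = function(x) x * stats::pnorm(x),
    g = function(x) stats::pnorm(x) + x * stats::dnorm(x),
    parameters = list()),
  Tanh = list(
    f = function(x) tanh(x),
    g = function(x) 1 - tanh(x)^2,
    parameters = list())
)

#' A named activation function
#'
#' `ActivationSpec` couples an activation name with its scalar map, its
#' derivative and any fixed constants (e.g. the SELU \eqn{\lambda, \alpha}).
#' `activationSpec()` builds one, either by looking up a built-in name or from
#' user-supplied functions, so the catalog is extensible beyond the defaults.
#'
#' @slot name single activation name.
#' @slot f scalar map, vectorised over numeric input.
#' @slot g derivative of `f`, vectorised; used by gradient-based trainers.
#' @slot parameters named list of fixed real constants.
#' @export
setClass("ActivationSpec",
  representation(name = "character", f = "function", g = "function",
                 parameters = "list"),
  validity = function(object) {
    if (length(object@name) != 1L || !nzchar(object@name))
      return("'name' must be a single non-empty string")
    probe <- object@f(c(-1, 0, 1))
    if (length(probe) != 3L || !all(is.finite(probe)))
      return("activation must be total and finite on finite input")
    TRUE
  })

#' @param name activation name. For the built-ins (`ReLU`, `ELU`, `SELU`,
#'   `Mish`, `SiLU`, `GELU`, `Tanh`) `f` and `g` may be omitted.
#' @param f scalar map (vectorised); required for non-built-in names.
#' @param g derivative of `f`; required for non-built-in names that will be
#'   used in gradient-based training.
#' @param parameters named list of fixed constants, for documentation only.
#' @return an `ActivationSpec`.
#' @rdname ActivationSpec-class
#' @examples
#' activationValue("Mish", 1)
#' sq <- activationSpec("Softsign", f = function(x) x / (1 + abs(x)),
#'                      g = function(x) 1 / (1 + abs(x))^2)
#' @export
activationSpec <- function(name, f = NULL, g = NULL, parameters = list()) {
  if (is.null(f)) {
    entry <- .afRegistry[[name]]
    if (is.null(entry))
      stop("unknown activation '", name, "' and no definition supplied", call. = FALSE)
    return(new("ActivationSpec", name = name, f = entry$f, g = entry$g,
               parameters = entry$parameters))
  }
  if (is.null(g)) g <- function(x) stop("no derivative defined for '", name, "'")
  new("ActivationSpec", name = name, f = f, g = g, parameters = parameters)
}

#' An ordered catalog of candidate activation functions
#'
#' The catalog is the `list_AF` of the switching controller: an ordered,
#' duplicate-free list of [ActivationSpec-class] objects. Order matters — it is
#' the tie-breaking key when probe losses are equal.
#'
#' @slot specs named list of `ActivationSpec`, in insertion order.
#' @export
setClass("ActivationCatalog", representation(specs = "list"),
  validity = function(object) {
    nm <- unname(vapply(object@specs, function(s) s@name, character(1)))
    if (length(nm) && !identical(names(object@specs), nm))
      return("specs must be named by their activation names")
    if (anyDuplicated(nm)) return("duplicate activation names in catalog")
    TRUE
  })

#' @param names character vector of activation names, or a list of
#'   `ActivationSpec` objects (mixing both is allowed).
#' @return an `ActivationCatalog`.
#' @rdname ActivationCatalog-class
#' @examples
#' cat6 <- activationCatalog(c("ReLU", "ELU", "SELU", "Mish", "SiLU", "GELU"))
#' names(cat6)
#' @export
activationCatalog <- function(names = defaultActivationNames()) {
  specs <- lapply(names, function(x) if (is(x, "ActivationSpec")) x else activationSpec(x))
  names(specs) <- vapply(specs, function(s) s@name, character(1))
  new("ActivationCatalog", specs = specs)
}

#' @return `defaultActivationNames()`: the six default candidates, in the order
#'   used throughout the package (`ReLU`, `ELU`, `SELU`, `Mish`, `SiLU`,
#'   `GELU`). `Tanh` is available in the registry but not a default candidate.
#' @rdname ActivationCatalog-class
#' @export
defaultActivationNames <- function() c("ReLU", "ELU", "SELU", "Mish", "SiLU", "GELU")

#' @export
setMethod("names", "ActivationCatalog", function(x) names(x@specs))

#' @export
setMethod("length", "ActivationCatalog", function(x) length(x@specs))

#' @export
setMethod("[[", "ActivationCatalog", function(x, i) {
  s <- x@specs[[i]]
  if (is.null(s)) stop("activation '", i, "' not in catalog", call. = FALSE)
  s
})

setMethod("show", "ActivationCatalog", function(object) {
  cat("ActivationCatalog with", length(object), "functions:",
      paste(names(object), collapse = ", "), "\n")
})

#' Evaluate an activation function
#'
#' Looks a name up in a catalog and applies the scalar map (`activationValue`)
#' or its derivative (`activationGradient`). All built-in definitions are the
#' standard published closed forms; see [ActivationSpec-class].
#'
#' @param name activation name present in `catalog`.
#' @param x numeric vector (finite).
#' @param catalog an [ActivationCatalog-class]; defaults to the full built-in
#'   registry (the six defaults plus `Tanh`).
#' @return numeric vector, same length as `x`.
#' @examples
#' activationValue("ReLU", -2)       # 0
#' activationValue("GELU", 0)        # 0
#' activationValue("Mish", 1)        # 0.8650984
#' @export
activationValue <- function(name, x, catalog = activationCatalog(names(.afRegistry))) {
  catalog[[name]]@f(x)
}

#' @rdname activationValue
#' @export
activationGradient <- function(name, x, catalog = activationCatalog(names(.afRegistry))) {
  catalog[[name]]@g(x)
}

#' Read or write a catalog as a plain-text list of names
#'
#' One activation name per line, order-significant; the serialisation is the
#' `list_AF` entry of a run configuration.
#'
#' @param path file path.
#' @param catalog an [ActivationCatalog-class].
#' @return `readCatalog` an `ActivationCatalog`; `writeCatalog` the path,
#'   invisibly.
#' @export
writeCatalog <- function(catalog, path) {
  writeLines(names(catalog), path)
  invisible(path)
}

#' @rdname writeCatalog
#' @export
readCatalog <- function(path) {
  nm <- trimws(readLines(path, warn = FALSE))
  activationCatalog(nm[nzchar(nm)])
}
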