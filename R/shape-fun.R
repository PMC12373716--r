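# Shape functions: real-valued functions on non-negative integers that are
# summed over a tree-shape sequence. A shape_fun carries its evaluator
# (vectorized in x, with optional extras n and ninner for higher-order
# functionals), a declared family, and the lower end of its domain.

#' Create a shape function
#'
#' @param fn A function of `x` (vectorized), optionally also of `n` (leaf
#'   count) and `ninner` (number of inner vertices) for higher-order
#'   functionals.
#' @param family Declared family: `"custom"`, `"affine"`, `"power"`, or
#'   `"log_shifted"`. Family constructors ([sf_affine()], [sf_power()],
#'   [sf_log()]) set this automatically; it feeds the closed-form extremal
#'   formulas and the recommendation logic.
#' @param params Named list of family parameters (e.g. `m`, `a` for affine).
#' @param domain_min Smallest integer argument on which `fn` is defined
#'   (e.g. 2 for `log(x - 1)`, matching the minimal clade size).
#' @param label Display label.
#' @return A `shape_fun`.
#' @export
shape_fun <- function(fn, family = "custom", params = list(), domain_min = 0,
                      label = NULL) {
  stopifnot(is.function(fn))
  fmls <- names(formals(fn))
  wrapped <- if (all(c("n", "ninner") %in% fmls)) {
    fn
  } else if ("n" %in% fmls) {
    function(x, n = NA_real_, ninner = NA_real_) fn(x, n = n)
  } else {
    function(x, n = NA_real_, ninner = NA_real_) fn(x)
  }
  structure(
    list(fn = wrapped, family = family, params = params,
         domain_min = domain_min,
         label = label %||% family),
    class = "shape_fun"
  )
}

#' @export
print.shape_fun <- function(x, ...) {
  cat(sprintf("<shape_fun %s (family %s, domain x >= %g)>\n",
              x$label, x$family, x$domain_min))
  invisible(x)
}

as_shape_fun <- function(f) {
  if (inherits(f, "shape_fun")) return(f)
  if (is.function(f)) return(shape_fun(f, label = "function"))
  if (is.character(f)) return(sf_expr(f))
  rlang::abort("expected a shape_fun, a function, or an expression string")
}

#' Built-in shape function families
#'
#' `sf_identity()` is `f(x) = x`; `sf_affine(m, a)` is `f(x) = m x + a`;
#' `sf_power(p)` is `f(x) = x^p`; `sf_log(base, scale, shift)` is
#' `f(x) = log_base(scale * x + shift)`. The classic index functions are
#' instances: the Sackin and Colless indices use the identity, the
#' quadratic Colless index uses `sf_power(2)`, and the s-hat statistic uses
#' `sf_log(shift = -1)` (defined from clade size 2 upward).
#'
#' @param m,a Slope and intercept of an affine function.
#' @param p Exponent.
#' @param base,scale,shift Parameters of `log_base(scale * x + shift)`.
#' @return A `shape_fun`.
#' @export
sf_identity <- function() {
  shape_fun(function(x) x, family = "affine", params = list(m = 1, a = 0),
            label = "x")
}

#' @rdname sf_identity
#' @export
sf_affine <- function(m, a = 0) {
  force(m); force(a)
  shape_fun(function(x) m * x + a, family = "affine",
            params = list(m = m, a = a),
            label = sprintf("%g*x + %g", m, a))
}

#' @rdname sf_identity
#' @export
sf_power <- function(p) {
  force(p)
  shape_fun(function(x) x^p, family = "power", params = list(p = p),
            label = sprintf("x^%g", p))
}

#' @rdname sf_identity
#' @export
sf_log <- function(base = exp(1), scale = 1, shift = 0) {
  force(base); force(scale); force(shift)
  # smallest integer x with scale*x + shift > 0
  dom <- max(0, ceiling((-shift) / scale + 1e-9))
  if (scale * dom + shift <= 0) dom <- dom + 1
  shape_fun(function(x) log(scale * x + shift, base = base),
            family = "log_shifted",
            params = list(base = base, scale = scale, shift = shift),
            domain_min = dom,
            label = sprintf("log_%g(%g*x + %g)", base, scale, shift))
}

#' Shape function from a safe arithmetic expression
#'
#' Parses an expression in `x` (and optionally `n`, `ninner`) with a fixed
#' operator whitelist, so expressions can be accepted from the command line
#' without arbitrary code execution.
#'
#' @param text Expression string, e.g. `"x^2"` or
#'   `"ifelse(x <= 3, x, x + 2)"`.
#' @param domain_min Smallest integer argument the expression is defined on.
#' @return A `shape_fun`.
#' @export
#' @examples
#' sf_expr("x / (x + 0.5)")
sf_expr <- function(text, domain_min = 0) {
  allowed_calls <- c("+", "-", "*", "/", "^", "(", "ifelse", "log", "log2",
                     "log10", "sqrt", "exp", "abs", "choose", "pmin", "pmax",
                     "<", "<=", ">", ">=", "==", "!=")
  allowed_syms <- c("x", "n", "ninner")
  expr <- tryCatch(str2lang(text), error = function(e) {
    rlang::abort(sprintf("cannot parse expression '%s': %s", text,
                         conditionMessage(e)))
  })
  check <- function(e) {
    if (is.numeric(e) || is.logical(e)) return(invisible(NULL))
    if (is.symbol(e)) {
      if (!as.character(e) %in% allowed_syms) {
        rlang::abort(sprintf("symbol '%s' is not allowed in shape function expressions",
                             as.character(e)))
      }
      return(invisible(NULL))
    }
    if (is.call(e)) {
      fname <- as.character(e[[1]])
      if (!fname %in% allowed_calls) {
        rlang::abort(sprintf("call to '%s' is not allowed in shape function expressions",
                             fname))
      }
      for (arg in as.list(e)[-1]) check(arg)
      return(invisible(NULL))
    }
    rlang::abort("unsupported construct in shape function expression")
  }
  check(expr)
  env <- new.env(parent = baseenv())
  fn <- function(x, n = NA_real_, ninner = NA_real_) {
    eval(expr, list(x = x, n = n, ninner = ninner), env)
  }
  shape_fun(fn, family = "custom", domain_min = domain_min, label = text)
}

#' Shape function of the total cophenetic index
#'
#' The third-order clade size functional
#' `f(x, n, ninner) = choose(x, 2) - choose(n, 2) / ninner`, which sums to
#' the total cophenetic index over the clade size sequence of any rooted
#' tree (second-order suffices on binary trees, where `ninner = n - 1`).
#'
#' @return A `shape_fun`.
#' @export
sf_total_cophenetic <- function() {
  shape_fun(function(x, n = NA_real_, ninner = NA_real_) {
    choose(x, 2) - choose(n, 2) / ninner
  }, family = "custom", label = "choose(x,2) - choose(n,2)/ninner")
}
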