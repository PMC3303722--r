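#' Fit a between-library regression normalization of miRNA expression
#'
#' Ordinary least squares of library B's expression on library A's over the
#' mature miRNAs expressed (count > 0) in both. The default scale is log10
#' — the model y = a*x + b then relates log-expression levels, which is the
#' natural scale for read counts spanning several orders of magnitude; a
#' linear-scale fit is available via \code{scale = "linear"}. After
#' fitting, the model is applied back to the fitting data and library B is
#' regressed on the normalized values: a post-normalization slope near 1
#' indicates most miRNAs agree between the libraries.
#'
#' @param expr_a,expr_b Expression data.frames from [expression_table()]
#'   (matched by \code{mature_id}), or numeric vectors of equal length.
#' @param scale "log10" (default) or "linear".
#' @return An object of class \code{norm_model}: slope, intercept,
#'   r_squared, post_slope, n_points, scale.
#' @export
fit_normalization <- function(expr_a, expr_b, scale = c("log10", "linear")) {
  scale <- match.arg(scale)
  if (is.data.frame(expr_a)) {
    shared <- intersect(expr_a$mature_id[expr_a$expression > 0],
                        expr_b$mature_id[expr_b$expression > 0])
    x <- expr_a$expression[match(shared, expr_a$mature_id)]
    y <- expr_b$expression[match(shared, expr_b$mature_id)]
  } else {
    keep <- expr_a > 0 & expr_b > 0
    x <- expr_a[keep]; y <- expr_b[keep]
  }
  if (length(x) < 3L) {
    stop("need at least 3 matures expressed in both libraries to fit; got ",
         length(x))
  }
  if (scale == "log10") {
    x <- log10(x); y <- log10(y)
  }
  fit <- stats::lm(y ~ x)
  model <- structure(list(slope = unname(stats::coef(fit)[2L]),
                          intercept = unname(stats::coef(fit)[1L]),
                          r_squared = stats::cor(x, y)^2,
                          post_slope = NA_real_,
                          n_points = length(x), scale = scale),
                     class = "norm_model")
  xn <- model$slope * x + model$intercept
  model$post_slope <- unname(stats::coef(stats::lm(y ~ xn))[2L])
  if (model$r_squared >= 0.8 &&
      (model$post_slope < 0.9 || model$post_slope > 1.1)) {
    warning("post-normalization slope ", signif(model$post_slope, 4),
            " outside [0.9, 1.1] despite R^2 >= 0.8")
  }
  model
}

#' @export
print.norm_model <- function(x, ...) {
  cat(sprintf("normalization model (%s scale): y = %.4fx %+.4f, R^2 = %.4f\n",
              x$scale, x$slope, x$intercept, x$r_squared))
  cat(sprintf("  n = %d shared miRNAs; post-normalization slope %.4f\n",
              x$n_points, x$post_slope))
  invisible(x)
}

#' Apply a fitted normalization model to expression values
#'
#' On the log10 scale each expression x maps to
#' 10^(slope*log10(x) + intercept); zero stays zero. Positive-slope models
#' preserve the rank order of expression.
#'
#' @param model A \code{norm_model}.
#' @param x Numeric vector of expression values (or an expression
#'   data.frame, whose \code{expression} column is transformed).
#' @return Same shape as \code{x}, normalized.
#' @export
apply_normalization <- function(model, x) {
  if (is.data.frame(x)) {
    x$expression <- apply_normalization(model, x$expression)
    return(x)
  }
  if (model$scale == "log10") {
    out <- ifelse(x > 0, 10^(model$slope * log10(pmax(x, .Machine$double.xmin))
                             + model$intercept), 0)
  } else {
    out <- model$slope * x + model$intercept
    out[x == 0] <- 0
  }
  out
}

#' Serialize / restore a normalization model as a key-value text file
#' @param model A \code{norm_model}.
#' @param path File path.
#' @return `path` invisibly (writer); a \code{norm_model} (reader).
#' @export
write_norm_model <- function(model, path) {
  lines <- c(sprintf("slope\t%.10g", model$slope),
             sprintf("intercept\t%.10g", model$intercept),
             sprintf("r_squared\t%.10g", model$r_squared),
             sprintf("post_slope\t%.10g", model$post_slope),
             sprintf("n_points\t%d", model$n_points),
             sprintf("scale\t%s", model$scale))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_norm_model
#' @export
read_norm_model <- function(path) {
  kv <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  vals <- stats::setNames(kv[[2L]], kv[[1L]])
  structure(list(slope = as.numeric(vals[["slope"]]),
                 intercept = as.numeric(vals[["intercept"]]),
                 r_squared = as.numeric(vals[["r_squared"]]),
                 post_slope = as.numeric(vals[["post_slope"]]),
                 n_points = as.integer(vals[["n_points"]]),
                 scale = vals[["scale"]]),
            class = "norm_model")
}
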