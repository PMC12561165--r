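#' @keywords internal
"_PACKAGE"

# The 12 diagnostic classes: 11 myocardial-infarction locations plus healthy control.
RTCN_CLASSES <- c("AMI", "ALMI", "ASMI", "ASLMI", "IMI", "ILMI", "IPMI",
                  "IPLMI", "LMI", "PMI", "PLMI", "HC")

#' Diagnostic class codes
#'
#' Returns the 12 class codes handled throughout the pipeline: 11 anatomical
#' myocardial-infarction locations (anterior, inferior, lateral, posterior and
#' their combinations) plus healthy control (\code{"HC"}).
#'
#' @return Character vector of length 12.
#' @export
rtcn_classes <- function() RTCN_CLASSES

stop_rtcn <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_rtcn(msg)
  invisible(TRUE)
}

check_class_code <- function(label, allow_unknown = FALSE) {
  ok <- label %in% RTCN_CLASSES | (allow_unknown & label == "unknown")
  if (!all(ok)) {
    stop_rtcn("unknown class code(s): ", paste(unique(label[!ok]), collapse = ", "),
              "; expected one of ", paste(RTCN_CLASSES, collapse = ", "))
  }
  invisible(TRUE)
}

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, evaluates \code{code}, and restores the caller's RNG state.
#' With \code{seed = NULL} the code runs under the current state.
#'
#' @param seed integer seed or NULL.
#' @param code expression to evaluate.
#' @return The value of \code{code}.
#' @export
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(code)
}

#' Derive a per-stage seed from a master seed
#'
#' A single master seed is fanned out deterministically to the pipeline stages
#' (a stage rerun in isolation sees the same seed it saw inside the full run).
#' The derived value always fits in a 32-bit integer.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return Integer seed.
#' @export
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 48271 + h * 16807) %% 2147483629L)
}

# Separable corner-aligned linear interpolation of a matrix to a new size.
# Used for model-input resizing and Grad-CAM upsampling: evaluating an
# upscaled image back at the original grid points is exact for (bi)linear data.
bilinear_resize <- function(mat, out_rows, out_cols) {
  stopifnot(is.matrix(mat), out_rows >= 1, out_cols >= 1)
  nr <- nrow(mat); nc <- ncol(mat)
  xi_r <- if (out_rows == 1 || nr == 1) rep(1, out_rows) else
    seq(1, nr, length.out = out_rows)
  xi_c <- if (out_cols == 1 || nc == 1) rep(1, out_cols) else
    seq(1, nc, length.out = out_cols)
  # rows first
  tmp <- if (nr == 1) matrix(rep(mat, each = out_rows), out_rows, nc) else
    apply(mat, 2, function(col) stats::approx(seq_len(nr), col, xout = xi_r)$y)
  tmp <- matrix(tmp, nrow = out_rows)
  out <- if (nc == 1) matrix(rep(tmp, times = out_cols), out_rows, out_cols) else
    t(apply(tmp, 1, function(row) stats::approx(seq_len(nc), row, xout = xi_c)$y))
  matrix(out, nrow = out_rows, ncol = out_cols)
}
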