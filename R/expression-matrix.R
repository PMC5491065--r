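#' Expression matrix container
#'
#' A probes x samples grid of expression values carrying its scale
#' (`"linear"` or `"log2"`) and processing stage (`"raw"`,
#' `"background_corrected"`, `"normalized"`, `"filtered"`). Stage
#' transitions are only allowed in that order; each pipeline step checks
#' the stage of its input so matrices cannot silently skip a step.
#'
#' @param values numeric matrix with probe ids as rownames and sample ids
#'   as colnames. No missing values are allowed.
#' @param scale one of `"linear"`, `"log2"`.
#' @param stage one of `"raw"`, `"background_corrected"`, `"normalized"`,
#'   `"filtered"`.
#' @return An object of class `"expr_matrix"`: a list with elements
#'   `values`, `scale`, `stage`.
#' @export
expr_matrix <- function(values, scale = c("linear", "log2"),
                        stage = c("raw", "background_corrected",
                                  "normalized", "filtered")) {
  scale <- match.arg(scale)
  stage <- match.arg(stage)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) {
    stop("expression matrix must not contain missing values")
  }
  if (is.null(rownames(values)) && nrow(values) > 0) {
    stop("expression matrix requires probe ids as rownames")
  }
  if (is.null(colnames(values)) && ncol(values) > 0) {
    stop("expression matrix requires sample ids as colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate probe ids in expression matrix")
  }
  structure(list(values = values, scale = scale, stage = stage),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d probes x %d samples [%s, %s]\n",
              nrow(x$values), ncol(x$values), x$scale, x$stage))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

stage_order <- c(raw = 1L, background_corrected = 2L, normalized = 3L,
                 filtered = 4L)

# stop unless the matrix is at `stage` and on `scale` (NULL = don't care)
check_matrix_state <- function(m, stage = NULL, scale = NULL, what = "input") {
  if (!inherits(m, "expr_matrix")) {
    stop(sprintf("%s must be an expr_matrix", what))
  }
  if (!is.null(stage) && !(m$stage %in% stage)) {
    stop(sprintf("%s must be at stage %s, got '%s'", what,
                 paste(sQuote(stage), collapse = " or "), m$stage))
  }
  if (!is.null(scale) && !(m$scale %in% scale)) {
    stop(sprintf("%s must be on the %s scale, got '%s'", what,
                 paste(sQuote(scale), collapse = " or "), m$scale))
  }
  invisible(m)
}

advance_stage <- function(m, to) {
  if (stage_order[[to]] < stage_order[[m$stage]]) {
    stop(sprintf("cannot move stage backwards from '%s' to '%s'", m$stage, to))
  }
  m$stage <- to
  m
}

#' Group labels of the three-group design
#'
#' The ordered group axis used throughout: embryonic stem cells (ES),
#' otospheres (OS), cochlear sensory epithelium (CSE). All per-group mean
#' vectors and templates follow this order.
#' @export
GROUPS <- c("ES", "OS", "CSE")
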