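#' Fossil calibration specifications
#'
#' A calibration constrains the age of the internal node that is the most
#' recent common ancestor of a named clade.  The single supported density
#' family is the soft-uniform bound: probability mass `1 - 2 * tail_prob`
#' is uniform on `[t_L, t_U]` and each side carries an exponentially
#' decaying tail of mass `tail_prob`, continuous at the bounds.
#'
#' @param clade character vector of leaf labels; their MRCA is calibrated.
#' @param t_L,t_U lower and upper bound ages, `0 <= t_L < t_U`.
#' @param tail_prob probability mass in each tail, in (0, 0.5).
#' @param kind density family; only `"soft_uniform"` is supported.
#' @return an object of class `calibration_spec`.
#' @export
calibration_spec <- function(clade, t_L, t_U, tail_prob = 0.025,
                             kind = "soft_uniform") {
  if (!identical(kind, "soft_uniform"))
    stop("unsupported calibration kind '", kind,
         "'; only soft_uniform bounds are implemented")
  if (!(t_L >= 0 && t_L < t_U)) stop("need 0 <= t_L < t_U")
  if (!(tail_prob > 0 && tail_prob < 0.5)) stop("tail_prob must be in (0, 0.5)")
  structure(list(clade = as.character(clade), kind = kind,
                 t_L = t_L, t_U = t_U, tail_prob = tail_prob),
            class = "calibration_spec")
}

#' Log density of a soft-uniform calibration bound
#'
#' The density has height `h0 = (1 - 2 p) / (t_U - t_L)` on the bounds and
#' tails `h0 * exp(+/- (t - bound) * h0 / p)` so each tail integrates to
#' `p = tail_prob` exactly (over the real line; the mass the left tail
#' places below age 0 is negligible for any realistic bound).
#'
#' @param spec a [calibration_spec()].
#' @param t age(s) at which to evaluate, > 0.
#' @return `ln f_cal(t)`, vectorized over `t`.
#' @export
calibration_logpdf <- function(spec, t) {
  p <- spec$tail_prob
  h0 <- (1 - 2 * p) / (spec$t_U - spec$t_L)
  rate <- h0 / p
  out <- numeric(length(t))
  lo <- t < spec$t_L
  hi <- t > spec$t_U
  out[lo] <- log(h0) + (t[lo] - spec$t_L) * rate
  out[hi] <- log(h0) - (t[hi] - spec$t_U) * rate
  out[!lo & !hi] <- log(h0)
  out
}

#' Read a calibration configuration file
#'
#' Plain-text blocks of the form
#' ```
#' [calibration] clade=A,B type=soft_uniform min=0.5 max=1.0 tail=0.025
#' ```
#' Key-value pairs may continue on following lines until the next
#' `[calibration]` header.  Lines starting with `#` are comments.
#'
#' @param path file path.
#' @return list of [calibration_spec()].
#' @export
read_calibration_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  blocks <- list()
  cur <- NULL
  flush <- function(cur, blocks) {
    if (!is.null(cur)) blocks[[length(blocks) + 1L]] <- cur
    blocks
  }
  for (ln in lines) {
    if (startsWith(ln, "[calibration]")) {
      blocks <- flush(cur, blocks)
      cur <- character(0)
      ln <- trimws(sub("^\\[calibration\\]", "", ln))
      if (!nzchar(ln)) next
    } else if (is.null(cur)) {
      stop("calibration config: content before first [calibration] block")
    }
    cur <- c(cur, strsplit(ln, "[[:space:]]+")[[1]])
  }
  blocks <- flush(cur, blocks)
  lapply(blocks, function(kv) {
    parts <- strsplit(kv, "=", fixed = TRUE)
    keys <- vapply(parts, `[`, "", 1L)
    vals <- vapply(parts, function(x) paste(x[-1], collapse = "="), "")
    names(vals) <- keys
    need <- c("clade", "min", "max")
    if (!all(need %in% keys))
      stop("calibration block missing key(s): ",
           paste(setdiff(need, keys), collapse = ", "))
    calibration_spec(
      clade = strsplit(vals[["clade"]], ",", fixed = TRUE)[[1]],
      t_L = as.numeric(vals[["min"]]), t_U = as.numeric(vals[["max"]]),
      tail_prob = if ("tail" %in% keys) as.numeric(vals[["tail"]]) else 0.025,
      kind = if ("type" %in% keys) vals[["type"]] else "soft_uniform")
  })
}

#' Write calibration specs in the config format read back by
#' [read_calibration_config()]
#' @param specs list of [calibration_spec()].
#' @param path output file path.
#' @export
write_calibration_config <- function(specs, path) {
  lines <- vapply(specs, function(s) {
    sprintf("[calibration] clade=%s type=%s min=%.17g max=%.17g tail=%.17g",
            paste(s$clade, collapse = ","), s$kind, s$t_L, s$t_U, s$tail_prob)
  }, "")
  writeLines(lines, path)
}

#' Resolve calibration clades to internal nodes
#'
#' Every spec's clade is mapped to its MRCA.  The root of the tree must
#' carry a calibration: the node-age prior conditions on the root age, so
#' an uncalibrated root would leave the time scale unanchored.
#'
#' @param tree a [species_tree].
#' @param specs list of [calibration_spec()].
#' @return named list mapping node id (as character) to its spec.
#' @export
resolve_calibrations <- function(tree, specs) {
  out <- list()
  for (s in specs) {
    v <- mrca_node(tree, s$clade)
    if (v <= tree$n_leaves)
      stop("calibration clade {", paste(s$clade, collapse = ","),
           "} resolves to a leaf, not an internal node")
    key <- as.character(v)
    if (!is.null(out[[key]]))
      stop("two calibrations resolve to the same node (",
           paste(s$clade, collapse = ","), ")")
    out[[key]] <- s
  }
  if (is.null(out[[as.character(tree$root)]]))
    stop("the root must carry a calibration (none of the clades spans all leaves)")
  out
}
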