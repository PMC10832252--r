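#' Per-variable orthogonal variance partition
#'
#' Assembles, for every column of the augmented matrix, the fraction of its
#' original (pre-adjustment) variance removed by each covariate projection,
#' the fraction captured by the net target-projection component, and the
#' residual. Because the parts are mutually orthogonal, each row sums to 1.
#' The outcome's net part is the variance of its net fitted values
#' \code{t_TP q_TP}; an explanatory variable's net part is the variance of
#' \code{t_TP p_i,TP}.
#'
#' @param state an \code{\link{adjustment_state}} after all projections.
#' @param net a \code{\link{net_model}} fitted on the same state (or NULL /
#'   a 0-component model, in which case the net part is zero everywhere).
#' @return object of class \code{"variance_partition"}: a numeric matrix
#'   (rows = variables, columns = one per projection, \code{"net"},
#'   \code{"residual"}) with attributes \code{roles} and \code{original_ss}.
#' @export
variance_partition <- function(state, net = NULL) {
  stopifnot(inherits(state, "adjustment_state"))
  cols <- colnames(state$aug)
  parts <- matrix(0, length(cols), state$n_CP + 2L,
                  dimnames = list(cols, c(rownames(state$ledger), "net", "residual")))
  oss <- state$original_ss
  if (state$n_CP > 0L)
    parts[, seq_len(state$n_CP)] <- t(state$ledger) / oss[cols]
  if (!is.null(net) && inherits(net, "net_model") && net$selected_A > 0L) {
    tp <- net$tp
    tt <- sum(tp$t^2)
    ex <- state$explanatory
    if (!all(tp$column_names == ex))
      stop("net model explanatory columns do not match the adjustment state")
    parts[ex, "net"] <- tt * tp$p^2 / oss[ex]
    parts[state$outcome, "net"] <- tt * tp$q^2 / oss[state$outcome]
  }
  parts[, "residual"] <- pmax(0, 1 - rowSums(parts[, -ncol(parts), drop = FALSE]))
  structure(parts, roles = state$roles, original_ss = oss,
            class = c("variance_partition", "matrix"))
}

#' Block-level remaining and explained variance table
#'
#' Aggregates per-variable variance partitions from a sequence of nested
#' adjustment stages into a table with, per named variable block and stage,
#' the remaining variance (100 minus all covariate parts) and the variance
#' explained by that stage's net target component, both in percent of the
#' original, pre-adjustment variance. Since variables enter standardised,
#' block aggregation is the plain mean over member variables.
#'
#' @param partitions named list of \code{\link{variance_partition}} objects,
#'   one per stage, in nesting order (first typically "unadjusted").
#' @param blocks named list of character vectors defining variable blocks
#'   (e.g. outcome, adiposity, physical activity).
#' @return data.frame with columns \code{stage}, then
#'   \code{remaining_<block>} and \code{explained_<block>} in percent.
#' @export
block_variance_table <- function(partitions, blocks) {
  stopifnot(is.list(partitions), is.list(blocks), length(names(blocks)) == length(blocks))
  rows <- lapply(seq_along(partitions), function(i) {
    vp <- partitions[[i]]
    vars_all <- rownames(vp)
    cov_cols <- setdiff(colnames(vp), c("net", "residual"))
    out <- list(stage = names(partitions)[i] %||% paste0("stage", i))
    for (bn in names(blocks)) {
      vars <- blocks[[bn]]
      if (!all(vars %in% vars_all))
        stop("block '", bn, "' has variables absent from stage ", i)
      sub <- vp[vars, , drop = FALSE]
      removed <- if (length(cov_cols)) rowSums(sub[, cov_cols, drop = FALSE]) else 0
      out[[paste0("remaining_", bn)]] <- 100 * mean(1 - removed)
      out[[paste0("explained_", bn)]] <- 100 * mean(sub[, "net"])
    }
    as.data.frame(out, check.names = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.variance_partition <- function(x, digits = 3, ...) {
  cat("Variance partition (fractions of original per-variable variance)\n")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Stacked-bar variance plot
#'
#' Displays, for each variable, the stacked fractions of original variance
#' attributed to each covariate projection, the net predictive component,
#' and the residual.
#'
#' @param x a \code{\link{variance_partition}}.
#' @param ... passed to \code{barplot}.
#' @export
plot.variance_partition <- function(x, ...) {
  m <- t(unclass(x))
  cols <- c(grDevices::hcl.colors(max(1L, nrow(m) - 1L), "Dark 3"), "grey85")
  op <- graphics::par(mar = c(8, 4, 2, 6), xpd = TRUE)
  on.exit(graphics::par(op))
  graphics::barplot(m, col = cols, border = NA, las = 2,
                    ylab = "fraction of original variance",
                    cex.names = 0.6, ...)
  graphics::legend("topright", inset = c(-0.15, 0), legend = rownames(m),
                   fill = cols, cex = 0.7, bty = "n")
  invisible(x)
}

#' Export a variance partition as a tidy data frame
#'
#' @param x a \code{\link{variance_partition}}.
#' @param ... unused.
#' @return data.frame with columns \code{variable}, \code{part},
#'   \code{fraction}.
#' @export
as.data.frame.variance_partition <- function(x, ...) {
  data.frame(variable = rep(rownames(x), ncol(x)),
             part = rep(colnames(x), each = nrow(x)),
             fraction = as.vector(unclass(x)),
             row.names = NULL)
}
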