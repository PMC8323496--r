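#' Estimate a moderated mixed graphical model
#'
#' Same nodewise-regression machinery as [estimate_network()], but every
#' design is augmented with three-way interaction terms involving the
#' designated moderator node: in the regression of node s (s not the
#' moderator) products of each other predictor's dummies with the
#' moderator's dummies; in the moderator's own regression products of all
#' predictor-pair dummies. EBIC selection applies to the enlarged
#' candidate set with the same gamma. A moderation edge for a pair (s, t)
#' is declared present when its interaction parameters survive the
#' combine rule across the three regressions that contain them (response
#' s, response t, response moderator).
#'
#' @param table a cohort table of categorical columns.
#' @param moderator name of the moderator node (must have at least two
#'   observed levels).
#' @param config an [estimation_config()].
#' @param nodes columns to use (default: all factor columns).
#' @return an object of class `mgm_moderated` (extends `mgm_network` with
#'   `moderator`, `interaction_blocks`, `mod_weights`, `mod_present`,
#'   `moderator_levels`).
#' @export
fit_moderated <- function(table, moderator, config = estimation_config(),
                          nodes = NULL) {
  nodes <- nodes %||% names(table)[vapply(table, is.factor, logical(1))]
  if (!moderator %in% nodes) stop_input("moderator must be one of the nodes")
  tab <- suppressMessages(complete_case_filter(table, nodes))[, nodes, drop = FALSE]
  if (nlevels(droplevels(factor(tab[[moderator]]))) < 2) {
    stop_input("moderator has a single observed level")
  }

  fits <- stats::setNames(vector("list", length(nodes)), nodes)
  for (nd in nodes) {
    ed <- encode_design(tab, nd, moderator = moderator)
    fits[[nd]] <- fit_nodewise(ed$y, ed$X, config, colmap = ed$colmap, node = nd)
  }
  base <- aggregate_edges(fits, config, n_used = nrow(tab))

  mod_levels <- levels(droplevels(factor(tab[[moderator]])))
  others <- setdiff(nodes, moderator)
  p <- length(nodes)
  MW <- matrix(0, p, p, dimnames = list(nodes, nodes))
  MP <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  iblocks <- list()

  if (length(others) >= 2) {
    prs <- utils::combn(others, 2, simplify = FALSE)
    for (pr in prs) {
      s <- pr[1]; t <- pr[2]
      b_s <- interaction_block(fits[[s]], t, moderator)   # K_s x (Lt-1) x (Lm-1)
      b_t <- interaction_block(fits[[t]], s, moderator)   # K_t x (Ls-1) x (Lm-1)
      b_m <- interaction_block_pair(fits[[moderator]], s, t) # K_m x (Ls-1) x (Lt-1)
      nz <- c(any(b_s != 0), any(b_t != 0), any(b_m != 0))
      present <- if (config$combine_rule == "AND") all(nz) else any(nz)
      iblocks[[edge_key(s, t)]] <- list(from_s = b_s, from_t = b_t,
                                        from_m = b_m, present = present)
      if (present) {
        MW[s, t] <- MW[t, s] <- mean(abs(c(b_s, b_t, b_m)))
      }
      MP[s, t] <- MP[t, s] <- present
    }
  }

  structure(c(base[setdiff(names(base), "moderator")],
              list(moderator = moderator, moderator_levels = mod_levels,
                   interaction_blocks = iblocks, mod_weights = MW,
                   mod_present = MP)),
            class = c("mgm_moderated", "mgm_network"))
}

# interaction coefficients of `fit` for predictor `other` moderated by `mod`,
# as an array (response levels) x (other levels - 1) x (moderator levels - 1)
interaction_block <- function(fit, other, mod) {
  cm <- fit$colmap
  sel <- which(cm$type == "inter" & cm$node1 == other & cm$node2 == mod)
  K <- nrow(fit$coefficients)
  if (!length(sel)) return(array(0, c(K, 0, 0)))
  l1 <- cm$level1[sel] - 1L; l2 <- cm$level2[sel] - 1L
  out <- array(0, c(K, max(l1), max(l2)))
  for (i in seq_along(sel)) out[, l1[i], l2[i]] <- fit$coefficients[, sel[i]]
  out
}

# interaction coefficients of the moderator's own regression for the pair
# (s, t), as an array (response levels) x (Ls - 1) x (Lt - 1)
interaction_block_pair <- function(fit, s, t) {
  cm <- fit$colmap
  sel <- which(cm$type == "inter" &
                 ((cm$node1 == s & cm$node2 == t) | (cm$node1 == t & cm$node2 == s)))
  K <- nrow(fit$coefficients)
  if (!length(sel)) return(array(0, c(K, 0, 0)))
  ls <- ifelse(cm$node1[sel] == s, cm$level1[sel], cm$level2[sel]) - 1L
  lt <- ifelse(cm$node1[sel] == s, cm$level2[sel], cm$level1[sel]) - 1L
  out <- array(0, c(K, max(ls), max(lt)))
  for (i in seq_along(sel)) out[, ls[i], lt[i]] <- fit$coefficients[, sel[i]]
  out
}

#' Condition a moderated network on one moderator level
#'
#' Substitutes a fixed moderator level into the moderated model: for each
#' pair not involving the moderator the effective cross-block at that
#' level is the pairwise block plus the interaction-block slice for the
#' level (the slice is zero at the moderator's reference level), and the
#' conditioned weight is the mean absolute value of the two effective
#' blocks. Edges involving the moderator itself keep their pairwise
#' weight, which does not vary across levels.
#'
#' @param model an `mgm_moderated`.
#' @param level moderator level label or 1-based level index.
#' @return symmetric weights matrix at that level.
#' @export
condition_on <- function(model, level) {
  stopifnot(inherits(model, "mgm_moderated"))
  lv <- model$moderator_levels
  if (is.character(level)) {
    li <- match(level, lv)
  } else li <- as.integer(level)
  if (is.na(li) || li < 1 || li > length(lv)) {
    stop_input("invalid moderator level; valid: ",
               paste(lv, collapse = ", "))
  }
  nodes <- model$nodes
  W <- model$weights # moderator edges and the skeleton carry over
  others <- setdiff(nodes, model$moderator)
  if (length(others) >= 2) {
    for (pr in utils::combn(others, 2, simplify = FALSE)) {
      s <- pr[1]; t <- pr[2]
      pw <- model$blocks[[edge_key(s, t)]]
      ib <- model$interaction_blocks[[edge_key(s, t)]]
      if (!pw$present && !ib$present) { # neither survives the combine rule
        W[s, t] <- W[t, s] <- 0
        next
      }
      eff_s <- pw$from_s
      eff_t <- pw$from_t
      if (li > 1) {
        if (length(ib$from_s)) eff_s <- eff_s + ib$from_s[, , li - 1]
        if (length(ib$from_t)) eff_t <- eff_t + ib$from_t[, , li - 1]
      }
      W[s, t] <- W[t, s] <- mean(abs(c(eff_s, eff_t)))
    }
  }
  W
}

#' Weights matrices conditioned on every moderator level
#' @param model an `mgm_moderated`.
#' @return named list of matrices, one per level.
#' @export
conditioned_weights <- function(model) {
  stats::setNames(lapply(seq_along(model$moderator_levels),
                         function(l) condition_on(model, l)),
                  model$moderator_levels)
}

#' @export
print.mgm_moderated <- function(x, ...) {
  NextMethod()
  nm <- sum(x$mod_present[upper.tri(x$mod_present)])
  cat(sprintf("  moderator: %s (%s); %d moderation edge(s)\n", x$moderator,
              paste(x$moderator_levels, collapse = "/"), nm))
  invisible(x)
}
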