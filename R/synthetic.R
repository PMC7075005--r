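#' The seven-target worked-example network
#'
#' The small TPT fixture used throughout the documentation and tests:
#' seven targets A..G in six pathways
#' a = \{A, B, C\}, b = \{B, C, E\}, c = \{B, E\}, d = \{C, D\},
#' e = \{C, F\}, f = \{F, G\}. Its one-mode projection has 8 edges and a
#' baseline network efficiency of 83/6 = 13.8333...; knocking out target C
#' drops the two size-3 pathways to 2/3 efficacy and the two size-2
#' pathways containing C to 1/2.
#'
#' @return A [bipartite_map()].
#' @export
#' @examples
#' network_efficiency(tpt_project(sample_network()))
sample_network <- function() {
  paths <- list(a = c("A", "B", "C"), b = c("B", "C", "E"),
                c = c("B", "E"), d = c("C", "D"),
                e = c("C", "F"), f = c("F", "G"))
  bipartite_map(unlist(paths, use.names = FALSE),
                rep(names(paths), lengths(paths)))
}

#' Random bipartite target-pathway map
#'
#' Generates a membership table with each (target, pathway) pair included
#' independently with probability `membership_prob`. Pathways falling below
#' `min_pathway_size` are handled per `small_pathways`: re-drawn (keeping
#' the requested pathway count; the default) or dropped. Size-1 pathways
#' are invisible to the TPT projection, so the default floor of 2 keeps
#' simulated pathway sizes inside the perturbation model's domain.
#'
#' @param n_targets number of targets (labelled T001, T002, ...).
#' @param n_pathways number of pathways (labelled P01, P02, ...).
#' @param membership_prob inclusion probability in (0, 1].
#' @param min_pathway_size minimum member count per pathway (default 2).
#' @param small_pathways `"redraw"` or `"drop"`.
#' @param seed integer seed; the same arguments and seed reproduce the map
#'   bit for bit.
#' @param max_retries redraw cap per pathway before an infeasibility error.
#' @return A [bipartite_map()].
#' @export
random_bipartite <- function(n_targets, n_pathways, membership_prob,
                             min_pathway_size = 2,
                             small_pathways = c("redraw", "drop"),
                             seed = 1L, max_retries = 100L) {
  small_pathways <- match.arg(small_pathways)
  stopifnot(n_targets >= 1, n_pathways >= 1,
            membership_prob > 0, membership_prob <= 1,
            min_pathway_size >= 0)
  if (min_pathway_size > n_targets) {
    stop("min_pathway_size exceeds the number of targets", call. = FALSE)
  }
  targets <- sprintf("T%03d", seq_len(n_targets))
  pathways <- sprintf("P%02d", seq_len(n_pathways))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  tg <- vector("list", n_pathways)
  keep <- rep(TRUE, n_pathways)
  for (j in seq_len(n_pathways)) {
    mem <- targets[stats::runif(n_targets) < membership_prob]
    if (small_pathways == "redraw") {
      tries <- 0L
      while (length(mem) < min_pathway_size) {
        tries <- tries + 1L
        if (tries > max_retries) {
          stop("could not draw a pathway of size >= ", min_pathway_size,
               " with membership_prob = ", membership_prob,
               " after ", max_retries, " retries", call. = FALSE)
        }
        mem <- targets[stats::runif(n_targets) < membership_prob]
      }
    } else if (length(mem) < min_pathway_size) {
      keep[j] <- FALSE
    }
    tg[[j]] <- mem
  }
  tg <- tg[keep]
  pathways <- pathways[keep]
  bipartite_map(unlist(tg), rep(pathways, lengths(tg)))
}

#' Synthetic literature co-occurrence counts
#'
#' Draws per-target counts from a Poisson log-linear model,
#' `count_i ~ Poisson(exp(baseline + beta * z_i))` with `z` the
#' standardized score, the simplest monotone count model: `beta = 0` gives
#' counts independent of the scores (a null for type-I checks), larger
#' `beta` gives a stronger monotone association (power checks). The default
#' `baseline = 1` puts the mean around e = 2.7 hits per target, in line
#' with formula-gene co-mention counts where most genes have few papers.
#'
#' @param scores numeric score vector (e.g. NED values), finite.
#' @param beta non-negative effect slope on the standardized score.
#' @param baseline log-scale intercept.
#' @param seed integer seed.
#' @return Integer vector of counts, same length as `scores`.
#' @export
synthetic_cooccurrence <- function(scores, beta = 0, baseline = 1,
                                   seed = 1L) {
  stopifnot(all(is.finite(scores)), beta >= 0)
  z <- if (length(scores) > 1 && stats::sd(scores) > 0) {
    (scores - mean(scores)) / stats::sd(scores)
  } else {
    rep(0, length(scores))
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  stats::rpois(length(scores), lambda = exp(baseline + beta * z))
}
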