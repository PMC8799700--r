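# Group-level inference on directed AU->AU causal links.
#
# For every matrix cell the distribution of GC strengths across real dyads
# is compared with an empirical null built from pseudo-dyads
# (patient-clinician pairings that never interacted but share the protocol
# structure) by a one-sided Mann-Whitney test (real > null), followed by
# Benjamini-Hochberg FDR correction across the 400 cells of each direction.

#' Enumerate pseudo-dyads from a roster
#'
#' All ordered pairings (patient of dyad i, clinician of dyad j), i != j -
#' `n (n - 1)` pseudo-dyads for `n` real dyads - optionally subsampled to
#' `cap` with a seeded uniform draw. A pseudo-dyad never repeats a real
#' pairing.
#'
#' @param roster a [dyad_roster()] with at least 2 real dyads.
#' @param cap optional maximum number of pseudo-dyads.
#' @param seed seed for the subsample.
#' @return a `dyad_roster` with `is_real = FALSE`.
#' @export
enumerate_pseudo_dyads <- function(roster, cap = NULL, seed = 1L) {
  real <- roster[roster$is_real, , drop = FALSE]
  if (nrow(real) < 2L) {
    stop("insufficient-data error: need >= 2 real dyads to build pseudo-dyads")
  }
  grid <- expand.grid(j = seq_len(nrow(real)), i = seq_len(nrow(real)))
  grid <- grid[grid$i != grid$j, c("i", "j")]
  grid <- grid[order(grid$i, grid$j), , drop = FALSE]
  ps <- dyad_roster(
    dyad_id = sprintf("pseudo_%s_x_%s", real$patient_id[grid$i],
                      real$clinician_id[grid$j]),
    patient_id = real$patient_id[grid$i],
    clinician_id = real$clinician_id[grid$j],
    is_real = FALSE)
  if (!is.null(cap) && cap < nrow(ps)) {
    set.seed(derive_seed(seed, "pseudo-cap", nrow(ps), cap))
    ps <- ps[sort(sample.int(nrow(ps), cap)), , drop = FALSE]
    rownames(ps) <- NULL
  }
  ps
}

#' One-sided Mann-Whitney cell test against the empirical null
#'
#' Tests whether the GC strengths across real dyads are stochastically
#' larger than the pseudo-dyad null (alternative `real > null`). The exact
#' rank-permutation distribution is used when `min(n, m) <= 8` and there
#' are no ties; otherwise the normal approximation with tie correction and
#' continuity correction. If every pooled value is identical the test is
#' degenerate and returns p = 1 (flagged).
#'
#' @param real GC strengths across real dyads (non-empty, finite).
#' @param null GC strengths across pseudo-dyads (non-empty, finite).
#' @param alternative test direction (default `"greater"`).
#' @return p value (with attribute `degenerate` when flagged).
#' @export
cell_test <- function(real, null, alternative = "greater") {
  if (!length(real) || !length(null)) {
    stop("empty-input error: both samples must be non-empty")
  }
  if (!all(is.finite(real)) || !all(is.finite(null))) {
    stop("data error: non-finite values in cell_test input")
  }
  pooled <- c(real, null)
  if (length(unique(pooled)) == 1L) {
    return(structure(1, degenerate = TRUE))
  }
  ties <- anyDuplicated(pooled) > 0L
  exact <- min(length(real), length(null)) <= 8L && !ties
  res <- suppressWarnings(
    stats::wilcox.test(real, null, alternative = alternative,
                       exact = exact, correct = TRUE)
  )
  unname(res$p.value)
}

#' Benjamini-Hochberg FDR correction over a p-value grid
#'
#' Step-up BH over the `m` non-missing cells (400 for a full direction
#' grid); a cell is significant when its q value is `<= alpha`.
#'
#' @param p numeric matrix (or vector) of p values in `[0, 1]`; `NA` cells
#'   are excluded and `m` reduced accordingly.
#' @param alpha FDR level.
#' @return object of class `sig_matrix` with `p`, `q`, `significant`
#'   grids, `alpha` and `m` (tests performed).
#' @export
fdr_correct <- function(p, alpha = 0.05) {
  pm <- as.matrix(p)
  ok <- !is.na(pm)
  if (any(pm[ok] < 0 | pm[ok] > 1)) {
    stop("data error: p values must lie in [0, 1]")
  }
  q <- pm
  q[ok] <- stats::p.adjust(pm[ok], method = "BH")
  sig <- ok & q <= alpha
  sig[!ok] <- NA
  structure(list(p = pm, q = q, significant = sig, alpha = alpha,
                 m = sum(ok)),
            class = "sig_matrix")
}

#' @export
print.sig_matrix <- function(x, ...) {
  cat(sprintf("<sig_matrix> %d tests, %d significant at FDR %g (min q = %.4g)\n",
              x$m, sum(x$significant, na.rm = TRUE), x$alpha,
              suppressWarnings(min(x$q, na.rm = TRUE))))
  invisible(x)
}

gc_array <- function(mats) {
  ms <- lapply(mats, function(m) if (inherits(m, "gc_matrix")) m$values else as.matrix(m))
  d <- dim(ms[[1L]])
  if (!all(vapply(ms, function(m) identical(dim(m), d), TRUE))) {
    stop("shape error: GC matrices have inconsistent dimensions")
  }
  array(unlist(ms), dim = c(d, length(ms)),
        dimnames = c(dimnames(ms[[1L]]), list(NULL)))
}

#' Cell-wise group test of real-dyad GC against the pseudo-dyad null
#'
#' Applies [cell_test()] to every matrix cell (real-dyad values vs
#' pseudo-dyad values, one-sided real > null) and corrects the resulting
#' grid with [fdr_correct()] across all cells of the direction.
#'
#' @param real list of `gc_matrix` (or plain matrices) across real dyads.
#' @param null list of `gc_matrix` across pseudo-dyads.
#' @param alpha FDR level.
#' @param alternative passed to [cell_test()].
#' @return a `sig_matrix` with additional fields `n_real`, `n_null` and
#'   `direction`.
#' @export
gc_group_test <- function(real, null, alpha = 0.05, alternative = "greater") {
  ra <- gc_array(real)
  na <- gc_array(null)
  if (!identical(dim(ra)[1:2], dim(na)[1:2])) {
    stop("shape error: real and null grids have different dimensions")
  }
  nr <- dim(ra)[1L]
  nc <- dim(ra)[2L]
  p <- matrix(NA_real_, nr, nc, dimnames = dimnames(ra)[1:2])
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      rv <- ra[i, j, ]
      nv <- na[i, j, ]
      rv <- rv[is.finite(rv)]
      nv <- nv[is.finite(nv)]
      if (length(rv) && length(nv)) {
        p[i, j] <- cell_test(rv, nv, alternative = alternative)
      }
    }
  }
  out <- fdr_correct(p, alpha)
  out$n_real <- dim(ra)[3L]
  out$n_null <- dim(na)[3L]
  dir <- if (inherits(real[[1L]], "gc_matrix")) real[[1L]]$direction else NULL
  out$direction <- dir
  out
}

#' Summarise significant directed links and the AU28 causality score
#'
#' Counts FDR-surviving links per direction, per-AU out-degrees (as source)
#' and in-degrees (as target), and the per-dyad scalar causality score of a
#' chosen patient source AU on the clinician's face: the mean GC strength
#' of that AU's matrix row across all 20 clinician target AUs (by default
#' AU28, lip suck - the top pain-discriminating feature).
#'
#' @param sig_p2c `sig_matrix` for the patient-to-clinician direction.
#' @param sig_c2p optional `sig_matrix` for the reverse direction.
#' @param gc_p2c optional list of real-dyad patient-to-clinician
#'   `gc_matrix` objects used for the per-dyad AU row score.
#' @param source_au AU label whose row is averaged.
#' @return object of class `link_summary`.
#' @export
summarize_links <- function(sig_p2c, sig_c2p = NULL, gc_p2c = NULL,
                            source_au = "AU28_lip_suck") {
  stopifnot(inherits(sig_p2c, "sig_matrix"))
  count_dir <- function(sig) sum(sig$significant, na.rm = TRUE)
  out_degree <- rowSums(sig_p2c$significant, na.rm = TRUE)
  in_degree <- colSums(sig_p2c$significant, na.rm = TRUE)
  n_c2p <- if (!is.null(sig_c2p)) {
    stopifnot(inherits(sig_c2p, "sig_matrix"))
    if (!identical(dim(sig_c2p$p), dim(sig_p2c$p))) {
      stop("shape error: direction grids have different dimensions")
    }
    count_dir(sig_c2p)
  } else {
    NA_integer_
  }
  au_scores <- NULL
  if (!is.null(gc_p2c)) {
    au_scores <- vapply(gc_p2c, function(m) {
      v <- if (inherits(m, "gc_matrix")) m$values else as.matrix(m)
      if (!source_au %in% rownames(v)) {
        stopf("schema error: source AU %s not found in matrix rows", source_au)
      }
      mean(v[source_au, ])
    }, 0)
    ids <- vapply(gc_p2c, function(m) {
      (if (inherits(m, "gc_matrix")) m$dyad_id else NULL) %||% NA_character_
    }, "")
    names(au_scores) <- ids
  }
  structure(list(n_links_patient_to_clinician = count_dir(sig_p2c),
                 n_links_clinician_to_patient = n_c2p,
                 out_degree = out_degree, in_degree = in_degree,
                 source_au = source_au, au_row_score = au_scores),
            class = "link_summary")
}

#' @export
print.link_summary <- function(x, ...) {
  cat(sprintf("<link_summary> patient->clinician: %d significant links; clinician->patient: %s\n",
              x$n_links_patient_to_clinician,
              ifelse(is.na(x$n_links_clinician_to_patient), "not tested",
                     format(x$n_links_clinician_to_patient))))
  top <- sort(x$out_degree, decreasing = TRUE)
  top <- top[top > 0]
  if (length(top)) {
    cat("  top source AUs (out-degree):",
        paste(sprintf("%s=%d", names(utils::head(top, 3)), utils::head(top, 3)),
              collapse = ", "), "\n")
  }
  if (!is.null(x$au_row_score)) {
    cat(sprintf("  %s row score: mean %.4f across %d dyads\n", x$source_au,
                mean(x$au_row_score), length(x$au_row_score)))
  }
  invisible(x)
}
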