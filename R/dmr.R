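# Probe-lasso style DMR calling: a dynamic, annotation-aware window is
# thrown around each significant probe; windows capturing enough
# significant neighbors are merged into regions whose p-values are
# combined and FDR-adjusted.

#' Parameters for DMR calling
#'
#' Defaults follow common probe-lasso settings: `lasso_style = "max"`,
#' `lasso_radius = 2000` bp, at least 2 significant probes per lasso,
#' 1000 bp minimum separation between regions, no minimum size, and a 10%
#' FDR on region q-values.
#'
#' @param lasso_style Aggregation of category radii: `"max"`, `"mean"` or
#'   `"min"`.
#' @param lasso_radius Target aggregate radius in bp.
#' @param min_sig_probes Minimum significant probes captured per lasso.
#' @param min_dmr_sep Minimum bp separation between distinct regions;
#'   closer regions merge.
#' @param min_dmr_size Minimum region size in bp.
#' @param adj_p_threshold FDR threshold on region q-values.
#' @param seed_p Unadjusted per-probe p-value cutoff seeding lassos.
#' @return A list of class `dmr_params`.
#' @export
dmr_params <- function(lasso_style = c("max", "mean", "min"),
                       lasso_radius = 2000, min_sig_probes = 2L,
                       min_dmr_sep = 1000, min_dmr_size = 0,
                       adj_p_threshold = 0.1, seed_p = 0.05) {
  lasso_style <- match.arg(lasso_style)
  assert_that(lasso_radius > 0 && min_dmr_sep > 0,
              "radii and separations must be positive")
  assert_that(adj_p_threshold > 0 && adj_p_threshold < 1,
              "adj_p_threshold must lie in (0, 1)")
  structure(list(lasso_style = lasso_style, lasso_radius = lasso_radius,
                 min_sig_probes = as.integer(min_sig_probes),
                 min_dmr_sep = min_dmr_sep, min_dmr_size = min_dmr_size,
                 adj_p_threshold = adj_p_threshold, seed_p = seed_p),
            class = "dmr_params")
}

#' Per-probe lasso radii from probe density
#'
#' Probes are grouped into feature x CpG-context categories (7 feature
#' labels by 4 context labels; missing labels form their own category).
#' Within each category the nearest-neighbor distance distribution is
#' summarized at a common quantile, chosen so that the aggregate of the
#' category radii under `lasso_style` equals `lasso_radius`; if no quantile
#' attains the target the radii are rescaled multiplicatively. Every probe
#' in a category shares its radius. Categories with fewer than 2 probes
#' get the global radius.
#'
#' @param annot Probe annotation with `chrom`, `pos`, `feature`,
#'   `cpg_context`.
#' @param params A [dmr_params()] object.
#' @return Named numeric vector of per-probe radii (bp).
#' @export
compute_lasso_radii <- function(annot, params = dmr_params()) {
  if (nrow(annot) == 0L)
    return(stats::setNames(numeric(), character()))
  ord <- order(annot$chrom, annot$pos)
  ann <- annot[ord, , drop = FALSE]

  # nearest-neighbor distance within chromosome
  nn <- rep(NA_real_, nrow(ann))
  for (ch in unique(ann$chrom)) {
    ix <- which(ann$chrom == ch)
    if (length(ix) < 2L) next
    d <- diff(ann$pos[ix])
    nn[ix] <- pmin(c(Inf, d), c(d, Inf))
  }
  nn[!is.finite(nn)] <- NA_real_

  feature <- ifelse(is.na(ann$feature), "missing", ann$feature)
  context <- ifelse(is.na(ann$cpg_context), "missing", ann$cpg_context)
  category <- paste(feature, context, sep = "|")
  cats <- split(seq_len(nrow(ann)), category)
  usable <- vapply(cats, function(ix) sum(!is.na(nn[ix])) >= 2L, logical(1))

  agg <- switch(params$lasso_style, max = max, mean = mean, min = min)
  cat_radius_at <- function(q) {
    vapply(cats[usable], function(ix)
      stats::quantile(nn[ix], q, na.rm = TRUE, names = FALSE), numeric(1))
  }
  radii_by_cat <- stats::setNames(rep(params$lasso_radius, length(cats)),
                                  names(cats))
  if (any(usable)) {
    f <- function(q) agg(cat_radius_at(q)) - params$lasso_radius
    if (f(1) <= 0) {
      r <- cat_radius_at(1)
      r <- r * params$lasso_radius / agg(r)
    } else if (f(0) >= 0) {
      r <- cat_radius_at(0)
      r <- r * params$lasso_radius / agg(r)
    } else {
      q_star <- stats::uniroot(f, c(0, 1), tol = 1e-6)$root
      r <- cat_radius_at(q_star)
    }
    radii_by_cat[names(r)] <- r
  }
  if (params$lasso_style == "max")
    radii_by_cat <- pmin(radii_by_cat, params$lasso_radius)

  out <- radii_by_cat[category]
  names(out) <- ann$probe_id
  out[annot$probe_id]  # restore input order
}

#' Combine p-values with Stouffer's method
#'
#' `z_i = qnorm(1 - p_i)`; combined p is `1 - pnorm(sum(z_i) / sqrt(k))`.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return A single combined p-value.
#' @export
combine_pvalues_stouffer <- function(p) {
  assert_that(length(p) >= 1L, "need at least one p-value")
  if (any(p <= 0)) {
    warnf("p-values of 0 clipped to machine minimum")
    p <- pmax(p, .Machine$double.xmin)
  }
  assert_that(all(p <= 1), "p-values must lie in (0, 1]")
  z <- stats::qnorm(1 - p)
  1 - stats::pnorm(sum(z) / sqrt(length(p)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values: `q_(i) = min_{j >= i} min(1, m p_(j) / j)`
#' over p-values sorted ascending.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values in input order.
#' @export
fdr_adjust <- function(p) {
  assert_that(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric())
  ord <- order(p)
  q_sorted <- pmin(1, p[ord] * m / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Call differentially methylated regions
#'
#' For each probe with unadjusted p below `params$seed_p` a lasso of its
#' per-probe radius is thrown; lassos capturing at least
#' `params$min_sig_probes` significant probes are kept, and kept lassos on
#' one chromosome that overlap or lie closer than `params$min_dmr_sep` are
#' merged into one region. Region p-values combine the member probes' p by
#' Stouffer's method; q-values are Benjamini-Hochberg. Regions with
#' `q < adj_p_threshold` and size at least `min_dmr_size` are returned.
#'
#' @param dmp_stats `data.frame` with columns `probe_id`, `chrom`, `pos`,
#'   `p`, sorted by (chrom, pos).
#' @param radii Per-probe radii from [compute_lasso_radii()], aligned by
#'   probe ID.
#' @param params A [dmr_params()] object.
#' @return A `data.frame` (class `dmr_result`) with columns `chrom`,
#'   `start`, `end` (1-based inclusive over member positions), `n_probes`,
#'   `n_significant`, `probe_ids` (semicolon-joined, position-sorted),
#'   `p_combined`, `q`.
#' @export
call_dmrs <- function(dmp_stats, radii, params = dmr_params()) {
  req <- c("probe_id", "chrom", "pos", "p")
  assert_that(all(req %in% colnames(dmp_stats)),
              "dmp_stats needs columns probe_id, chrom, pos, p")
  ord <- order(dmp_stats$chrom, dmp_stats$pos)
  if (!identical(ord, seq_len(nrow(dmp_stats))))
    stopf("dmp_stats must be sorted by (chrom, pos)")
  r <- radii[dmp_stats$probe_id]
  assert_that(!anyNA(r), "radii missing for some probes")

  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_probes = integer(),
                      n_significant = integer(), probe_ids = character(),
                      p_combined = numeric(), q = numeric(),
                      stringsAsFactors = FALSE)
  sig <- dmp_stats$p < params$seed_p
  if (!any(sig)) return(structure(empty, class = c("dmr_result", "data.frame")))

  regions <- list()
  for (ch in unique(dmp_stats$chrom)) {
    on_ch <- dmp_stats$chrom == ch
    pos <- dmp_stats$pos[on_ch]
    p_ch <- dmp_stats$p[on_ch]
    sig_ch <- sig[on_ch]
    r_ch <- r[on_ch]
    ids <- dmp_stats$probe_id[on_ch]
    sig_pos <- pos[sig_ch]

    # kept lassos: windows around significant probes capturing enough
    # significant neighbors
    kept <- list()
    for (i in which(sig_ch)) {
      lo <- pos[i] - r_ch[i]; hi <- pos[i] + r_ch[i]
      if (sum(sig_pos >= lo & sig_pos <= hi) >= params$min_sig_probes)
        kept[[length(kept) + 1L]] <- c(lo, hi)
    }
    if (!length(kept)) next
    kept <- do.call(rbind, kept)
    kept <- kept[order(kept[, 1]), , drop = FALSE]

    # merge overlapping/near windows
    merged <- list(kept[1, ])
    if (nrow(kept) > 1L) for (i in 2:nrow(kept)) {
      last <- merged[[length(merged)]]
      if (kept[i, 1] <= last[2] + params$min_dmr_sep) {
        merged[[length(merged)]] <- c(last[1], max(last[2], kept[i, 2]))
      } else merged[[length(merged) + 1L]] <- kept[i, ]
    }
    for (w in merged) {
      in_w <- pos >= w[1] & pos <= w[2]
      member_pos <- pos[in_w]
      regions[[length(regions) + 1L]] <- list(
        chrom = ch, start = min(member_pos), end = max(member_pos),
        n_probes = sum(in_w), n_significant = sum(in_w & sig_ch),
        probe_ids = paste(ids[in_w][order(member_pos)], collapse = ";"),
        p_combined = combine_pvalues_stouffer(p_ch[in_w]))
    }
  }
  if (!length(regions))
    return(structure(empty, class = c("dmr_result", "data.frame")))
  res <- do.call(rbind, lapply(regions, as.data.frame,
                               stringsAsFactors = FALSE))
  res$q <- fdr_adjust(res$p_combined)
  res <- res[res$q < params$adj_p_threshold &
               (res$end - res$start + 1L) >= params$min_dmr_size, ,
             drop = FALSE]
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("dmr_result", "data.frame"))
}

#' Export DMRs as BED intervals
#'
#' Converts the 1-based inclusive DMR intervals to BED's 0-based
#' half-open convention.
#'
#' @param dmrs A `dmr_result`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  bed <- data.frame(chrom = dmrs$chrom, start = dmrs$start - 1L,
                    end = dmrs$end,
                    name = sprintf("DMR%03d", seq_len(nrow(dmrs))),
                    score = round(-10 * log10(pmax(dmrs$p_combined,
                                                   1e-30))))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
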