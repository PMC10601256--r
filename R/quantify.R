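# qPCR quantification utilities: delta-delta-Ct relative expression,
# ChIP double normalization (percent input, then IgG), and CLIP RNA
# recovery. Amplification efficiency defaults to the classic factor 2 per
# cycle; it is exposed but not corrected per assay.

#' Read a Ct table from TSV/CSV
#'
#' Expected columns (extra columns pass through): sample, condition, gene,
#' ct; optional: is_reference (logical), antibody (`target`, `IgG`,
#' `input`, `none`), fraction (fraction of material, e.g. 0.01 for a 1
#' percent input), experiment, amplicon.
#'
#' @param path file path; delimiter inferred from the extension.
#' @return data.frame.
#' @export
read_ct_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("sample", "condition", "gene", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("read_ct_table: missing columns: ", paste(miss, collapse = ", "))
  }
  if (any(!is.finite(df$ct)) || any(df$ct <= 0)) {
    stop("read_ct_table: Ct values must be finite and > 0")
  }
  df
}

#' Relative expression by the delta-delta-Ct method
#'
#' `dCt = Ct_target - Ct_reference` per sample;
#' `ddCt = dCt_sample - mean(dCt of the control condition)`; relative
#' expression is `efficiency^-ddCt`. By construction the control
#' condition averages to 1 (geometric mean).
#'
#' @param table data.frame with columns sample, condition, gene, ct.
#' @param target target gene name.
#' @param reference reference (housekeeping) gene name (default
#'   `"Atp5bp"`).
#' @param control_condition condition normalized to (default
#'   `"ctrl-Fc"`).
#' @param efficiency per-cycle amplification factor (default 2).
#' @return data.frame: sample, condition, dct, ddct, fold_change.
#' @export
ddct_expression <- function(table, target, reference = "Atp5bp",
                            control_condition = "ctrl-Fc",
                            efficiency = 2) {
  tg <- table[table$gene == target, c("sample", "condition", "ct")]
  rf <- table[table$gene == reference, c("sample", "ct")]
  if (nrow(tg) == 0L) stop("ddct_expression: no rows for target ", target)
  if (nrow(rf) == 0L) {
    stop("ddct_expression: reference gene '", reference, "' missing")
  }
  m <- merge(tg, rf, by = "sample", suffixes = c("_target", "_ref"))
  if (nrow(m) < nrow(tg)) {
    stop("ddct_expression: reference Ct missing for some samples")
  }
  m$dct <- m$ct_target - m$ct_ref
  ctrl <- m$condition == control_condition
  if (!any(ctrl)) {
    stop("ddct_expression: no samples in control condition '",
         control_condition, "'")
  }
  m$ddct <- m$dct - mean(m$dct[ctrl])
  m$fold_change <- efficiency^(-m$ddct)
  m[, c("sample", "condition", "dct", "ddct", "fold_change")]
}

# percent-input recovery for one IP against its input row, with the
# material-fraction correction Ct_input_adj = Ct_input - log2(f_IP/f_input)
.recovery <- function(ct_ip, f_ip, ct_input, f_input, efficiency = 2) {
  adj <- ct_input - log(f_ip / f_input, base = efficiency)
  efficiency^(adj - ct_ip)
}

#' ChIP-qPCR fold enrichment by double normalization
#'
#' Recovery (percent input) is computed for the target antibody and for
#' IgG against the input row, correcting for the material fractions (e.g.
#' 1 percent input vs 20 percent per IP); fold enrichment is
#' `recovery_target / recovery_IgG`. A zero/absent IgG recovery is
#' reported as `Inf` with `infinite_enrichment = TRUE`, not an error.
#'
#' @param table data.frame with columns condition, antibody (`target`,
#'   `IgG`, `input`), fraction, ct and optionally amplicon/experiment.
#' @param experiment optional value to filter the `experiment` column on.
#' @param efficiency per-cycle amplification factor (default 2).
#' @return data.frame per (amplicon, condition): recovery_target,
#'   recovery_igg (both fractions of input material), fold_enrichment,
#'   infinite_enrichment.
#' @export
chip_fold_enrichment <- function(table, experiment = NULL, efficiency = 2) {
  if (!is.null(experiment)) table <- table[table$experiment == experiment, ]
  if (!"amplicon" %in% names(table)) table$amplicon <- "amplicon1"
  need <- c("condition", "antibody", "fraction", "ct")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("chip_fold_enrichment: missing columns: ",
         paste(miss, collapse = ", "))
  }
  keys <- unique(table[, c("amplicon", "condition")])
  rows <- lapply(seq_len(nrow(keys)), function(k) {
    sub <- table[table$amplicon == keys$amplicon[k] &
                   table$condition == keys$condition[k], ]
    pick <- function(ab) sub[sub$antibody == ab, , drop = FALSE]
    inp <- pick("input"); tgt <- pick("target"); igg <- pick("IgG")
    if (nrow(inp) != 1L || nrow(tgt) != 1L || nrow(igg) != 1L) {
      stop("chip_fold_enrichment: need exactly one input/target/IgG row ",
           "per amplicon and condition (", keys$amplicon[k], ", ",
           keys$condition[k], ")")
    }
    rt <- .recovery(tgt$ct, tgt$fraction, inp$ct, inp$fraction, efficiency)
    ri <- .recovery(igg$ct, igg$fraction, inp$ct, inp$fraction, efficiency)
    data.frame(
      amplicon = keys$amplicon[k], condition = keys$condition[k],
      recovery_target = rt, recovery_igg = ri,
      fold_enrichment = if (ri > 0) rt / ri else Inf,
      infinite_enrichment = ri <= 0,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' CLIP RNA recovery relative to total RNA
#'
#' Recovery of pulled-down RNA as a fraction of the total RNA of the same
#' experiment and condition, with the material-fraction correction; IgG
#' rows are reported alongside as the noise floor.
#'
#' @param table data.frame with columns condition, antibody (`target`,
#'   `IgG`, `input` = total RNA), fraction, ct, optional
#'   amplicon/experiment.
#' @param experiment optional filter on the `experiment` column.
#' @param efficiency per-cycle amplification factor (default 2).
#' @return data.frame per (amplicon, condition, antibody in target/IgG):
#'   recovery.
#' @export
clip_recovery <- function(table, experiment = NULL, efficiency = 2) {
  if (!is.null(experiment)) table <- table[table$experiment == experiment, ]
  if (!"amplicon" %in% names(table)) table$amplicon <- "amplicon1"
  keys <- unique(table[, c("amplicon", "condition")])
  rows <- list()
  for (k in seq_len(nrow(keys))) {
    sub <- table[table$amplicon == keys$amplicon[k] &
                   table$condition == keys$condition[k], ]
    inp <- sub[sub$antibody == "input", , drop = FALSE]
    if (nrow(inp) != 1L) {
      stop("clip_recovery: total-RNA (input) row missing for (",
           keys$amplicon[k], ", ", keys$condition[k], ")")
    }
    for (ab in c("target", "IgG")) {
      ip <- sub[sub$antibody == ab, , drop = FALSE]
      if (nrow(ip) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        amplicon = keys$amplicon[k], condition = keys$condition[k],
        antibody = ab,
        recovery = .recovery(ip$ct, ip$fraction, inp$ct, inp$fraction,
                             efficiency),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
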