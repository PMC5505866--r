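#' Classify Xenopus transcripts into memory and reprogrammed classes
#'
#' Implements the DE filter strategy over the three contrasts (Donor/IVF,
#' NT/IVF, Donor/NT), with every threshold comparison strict (boundary
#' values fail):
#' \describe{
#'   \item{ON_memory}{FDR Donor/IVF < alpha, logFC Donor/IVF > 0, FDR NT/IVF
#'     < alpha, logFC NT/IVF > 0, RPKM > `rpkm_cut` in all donor samples;
#'     the 3FC subclass additionally requires logFC NT/IVF > `fc3_log2`.}
#'   \item{OFF_memory}{FDR Donor/IVF < alpha, logFC Donor/IVF < 0, FDR
#'     NT/IVF < alpha, logFC NT/IVF < 0; the 3FC subclass additionally
#'     requires FDR Donor/NT < alpha, logFC Donor/NT < 0 and logFC NT/IVF <
#'     -`fc3_log2`.}
#'   \item{reprogrammed_down}{FDR Donor/IVF < alpha, logFC Donor/IVF > 0,
#'     FDR Donor/NT < alpha, logFC Donor/NT > 0, donor RPKM clause, and
#'     NT/IVF not significant — except that transcripts expressed in the
#'     donor (RPKM > cut in every donor sample) but not in IVF and NT (at
#'     least one IVF and one NT sample below the cut) are kept regardless of
#'     the NT/IVF exclusion, as they were successfully downregulated.}
#'   \item{reprogrammed_up}{mirrored, requiring FDR NT/IVF > alpha.}
#'   \item{reprogrammed}{significant Donor/IVF and Donor/NT with NT/IVF
#'     significance excluded, when neither directional rule applies.}
#'   \item{resistant_other_up / _down}{significant and sign-discordant in
#'     Donor/IVF vs NT/IVF, split by the sign of logFC NT/IVF (the "too
#'     much up/downregulated" groups of the resistant set).}
#' }
#' Rules are evaluated in a fixed order (memory classes, then reprogrammed,
#' then resistant_other, then unclassified) and each transcript gets exactly
#' one primary class; the `provenance` column records every clause set that
#' fired.
#'
#' @param de named list with elements `Donor_vs_IVF`, `NT_vs_IVF`,
#'   `Donor_vs_NT`, each a `de_result` over the same transcripts.
#' @param rpkm RPKM matrix over (at least) the donor samples.
#' @param samples sample sheet matching the RPKM columns.
#' @param fdr_alpha significance cutoff (strict <), default 0.05.
#' @param fc3_log2 log2 cutoff of the 3FC subclass (strict >), default 1.5
#'   (a 2^1.5 = 2.83-fold change, approximately 3-fold).
#' @param rpkm_cut donor expression cutoff (strict >), default 1.
#' @return A data.frame of class `memory_labels`: `transcript_id`,
#'   `primary_class`, `fc3_flag`, `provenance`.
#' @export
classify_xenopus <- function(de, rpkm, samples, fdr_alpha = 0.05,
                             fc3_log2 = 1.5, rpkm_cut = 1) {
  need <- c("Donor_vs_IVF", "NT_vs_IVF", "Donor_vs_NT")
  if (!all(need %in% names(de)))
    stop2("de must be a named list with contrasts: ",
          paste(need, collapse = ", "))
  ids <- de$Donor_vs_IVF$transcript_id
  for (ct in need[-1]) {
    if (!identical(de[[ct]]$transcript_id, ids))
      stop2("contrast ", ct, " covers a different transcript set")
  }
  if (!all(ids %in% rownames(rpkm)))
    stop2("RPKM matrix is missing transcripts present in the DE results")
  rpkm <- rpkm[ids, , drop = FALSE]

  di <- de$Donor_vs_IVF
  ni <- de$NT_vs_IVF
  dn <- de$Donor_vs_NT
  sig_di <- di$fdr < fdr_alpha
  sig_ni <- ni$fdr < fdr_alpha
  sig_dn <- dn$fdr < fdr_alpha

  donor_cols <- samples$sample_id[samples$group == "donor"]
  if (length(donor_cols) == 0) stop2("no donor samples in sample sheet")
  donor_expr <- rowSums(rpkm[, donor_cols, drop = FALSE] <= rpkm_cut) == 0

  ivf_cols <- samples$sample_id[samples$group == "IVF_ectoderm"]
  nt_cols <- samples$sample_id[samples$group == "NT_ectoderm"]
  have_ect <- length(ivf_cols) > 0 && length(nt_cols) > 0 &&
    all(c(ivf_cols, nt_cols) %in% colnames(rpkm))
  donor_only <- if (have_ect) {
    donor_expr &
      rowSums(rpkm[, ivf_cols, drop = FALSE] < rpkm_cut) > 0 &
      rowSums(rpkm[, nt_cols, drop = FALSE] < rpkm_cut) > 0
  } else rep(FALSE, length(ids))

  on_mem <- sig_di & di$logFC > 0 & sig_ni & ni$logFC > 0 & donor_expr
  on_mem3 <- on_mem & ni$logFC > fc3_log2
  off_mem <- sig_di & di$logFC < 0 & sig_ni & ni$logFC < 0
  off_mem3 <- off_mem & sig_dn & dn$logFC < 0 & ni$logFC < -fc3_log2
  rep_down_base <- sig_di & di$logFC > 0 & sig_dn & dn$logFC > 0 & donor_expr
  rep_down <- rep_down_base & (!sig_ni | donor_only)
  rep_up <- sig_di & di$logFC < 0 & sig_dn & dn$logFC < 0 &
    ni$fdr > fdr_alpha
  rep_any <- sig_di & sig_dn & !sig_ni
  discordant <- sig_di & sig_ni & sign(di$logFC) * sign(ni$logFC) < 0
  res_up <- discordant & ni$logFC > 0
  res_down <- discordant & ni$logFC < 0

  cls <- rep("unclassified", length(ids))
  fc3 <- rep(FALSE, length(ids))
  assign_cls <- function(mask, label) {
    hit <- mask & cls == "unclassified"
    cls[hit] <<- label
    hit
  }
  assign_cls(on_mem, "ON_memory")
  assign_cls(off_mem, "OFF_memory")
  assign_cls(rep_down, "reprogrammed_down")
  assign_cls(rep_up, "reprogrammed_up")
  assign_cls(rep_any, "reprogrammed")
  assign_cls(res_up, "resistant_other_up")
  assign_cls(res_down, "resistant_other_down")
  fc3[cls == "ON_memory" & on_mem3] <- TRUE
  fc3[cls == "OFF_memory" & off_mem3] <- TRUE

  prov_parts <- cbind(ON_memory = on_mem, ON_memory_3FC = on_mem3,
                      OFF_memory = off_mem, OFF_memory_3FC = off_mem3,
                      reprogrammed_down = rep_down,
                      reprogrammed_up = rep_up,
                      reprogrammed = rep_any,
                      resistant_other_up = res_up,
                      resistant_other_down = res_down,
                      donor_only_expressed = donor_only)
  prov <- apply(prov_parts, 1, function(r) {
    paste(colnames(prov_parts)[r], collapse = ";")
  })
  memory_labels(ids, cls, fc3, prov)
}

#' Classify human transcripts by fold change only
#'
#' The fold-change-only variant used where replicate structure does not
#' support FDRs. Thresholds are log2 units applied strictly as printed
#' (2.3, not log2(5)):
#' \describe{
#'   \item{ON_memory, >5FC}{logFC Donor/IVF > 2.3, logFC NT/IVF > 2.3,
#'     donor FPKM > 1.}
#'   \item{ON_memory, 2-5FC}{logFC Donor/IVF > 2.3, 1 < logFC NT/IVF < 2.3,
#'     donor FPKM > 1.}
#'   \item{OFF_memory, >5FC}{logFC Donor/IVF < -2.3, logFC NT/IVF < -2.3.}
#'   \item{OFF_memory, 2-5FC}{logFC Donor/IVF < -2.3,
#'     -2.3 < logFC NT/IVF < -1.}
#'   \item{reprogrammed_down}{logFC Donor/IVF > 2.3, donor FPKM > 1,
#'     excluding logFC NT/IVF > 1 (upper tail only).}
#'   \item{reprogrammed_up}{logFC Donor/IVF < -2.3, logFC NT/IVF > -1.}
#' }
#' `fc3_flag` carries the strong (>5FC) subclass; the `subclass` column
#' distinguishes `gt5FC` from `fc2to5`.
#'
#' @param input data.frame with columns `transcript_id`,
#'   `logFC_donor_vs_IVF`, `logFC_NT_vs_IVF` and `donor_fpkm` (a single
#'   value per transcript, or the minimum over donor samples).
#' @param fc_strong_log2 strong threshold, default 2.3.
#' @param fc_weak_log2 weak threshold, default 1.
#' @param fpkm_cut donor expression cutoff (strict >), default 1.
#' @return A `memory_labels` data.frame with an extra `subclass` column.
#' @export
classify_human <- function(input, fc_strong_log2 = 2.3, fc_weak_log2 = 1,
                           fpkm_cut = 1) {
  need <- c("transcript_id", "logFC_donor_vs_IVF", "logFC_NT_vs_IVF",
            "donor_fpkm")
  if (!all(need %in% names(input)))
    stop2("input needs columns: ", paste(need, collapse = ", "))
  if (any(input$donor_fpkm < 0)) stop2("FPKM must be nonnegative")
  if (any(!is.finite(input$logFC_donor_vs_IVF)) ||
      any(!is.finite(input$logFC_NT_vs_IVF)))
    stop2("logFCs must be finite (use a pseudocount upstream)")
  di <- input$logFC_donor_vs_IVF
  ni <- input$logFC_NT_vs_IVF
  donor_expr <- input$donor_fpkm > fpkm_cut

  on5 <- di > fc_strong_log2 & ni > fc_strong_log2 & donor_expr
  on25 <- di > fc_strong_log2 & ni > fc_weak_log2 & ni < fc_strong_log2 &
    donor_expr
  off5 <- di < -fc_strong_log2 & ni < -fc_strong_log2
  off25 <- di < -fc_strong_log2 & ni > -fc_strong_log2 & ni < -fc_weak_log2
  rep_down <- di > fc_strong_log2 & donor_expr & !(ni > fc_weak_log2)
  rep_up <- di < -fc_strong_log2 & ni > -fc_weak_log2

  n <- nrow(input)
  cls <- rep("unclassified", n)
  sub <- rep(NA_character_, n)
  set <- function(mask, label, subclass = NA_character_) {
    hit <- mask & cls == "unclassified"
    cls[hit] <<- label
    sub[hit] <<- subclass
    hit
  }
  set(on5, "ON_memory", "gt5FC")
  set(on25, "ON_memory", "fc2to5")
  set(off5, "OFF_memory", "gt5FC")
  set(off25, "OFF_memory", "fc2to5")
  set(rep_down, "reprogrammed_down")
  set(rep_up, "reprogrammed_up")

  prov_parts <- cbind(ON_gt5FC = on5, ON_2to5FC = on25, OFF_gt5FC = off5,
                      OFF_2to5FC = off25, reprogrammed_down = rep_down,
                      reprogrammed_up = rep_up)
  prov <- apply(prov_parts, 1, function(r) {
    paste(colnames(prov_parts)[r], collapse = ";")
  })
  out <- memory_labels(input$transcript_id, cls,
                       !is.na(sub) & sub == "gt5FC", prov)
  out$subclass <- sub
  out
}

memory_labels <- function(ids, primary_class, fc3_flag, provenance) {
  if (any(fc3_flag & !primary_class %in% c("ON_memory", "OFF_memory")))
    stop2("fc3_flag only applies to memory classes")
  out <- data.frame(transcript_id = ids,
                    primary_class = primary_class,
                    fc3_flag = fc3_flag,
                    provenance = provenance,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("memory_labels", "data.frame")
  out
}

#' Intersect classifications from replicate experiments
#'
#' A transcript keeps a class only if it received that same class in every
#' experiment; otherwise it becomes `unclassified`. The 3FC flag is
#' intersected too (kept only if flagged everywhere).
#'
#' @param labels_per_experiment list of at least two `memory_labels` over the
#'   same transcript universe.
#' @return A single `memory_labels` data.frame.
#' @export
intersect_replicates <- function(labels_per_experiment) {
  if (length(labels_per_experiment) < 2)
    stop2("need at least two experiments to intersect")
  ids <- labels_per_experiment[[1]]$transcript_id
  for (lab in labels_per_experiment[-1]) {
    if (!setequal(lab$transcript_id, ids))
      stop2("experiments cover different transcript universes")
  }
  aligned <- lapply(labels_per_experiment, function(lab) {
    lab[match(ids, lab$transcript_id), ]
  })
  cls_mat <- vapply(aligned, function(lab) lab$primary_class,
                    character(length(ids)))
  fc3_mat <- vapply(aligned, function(lab) lab$fc3_flag,
                    logical(length(ids)))
  agree <- apply(cls_mat, 1, function(r) all(r == r[1]))
  cls <- ifelse(agree, cls_mat[, 1], "unclassified")
  fc3 <- agree & apply(fc3_mat, 1, all) &
    cls %in% c("ON_memory", "OFF_memory")
  memory_labels(ids, cls, fc3,
                ifelse(agree, "intersect:agree", "intersect:conflict"))
}

#' Exclude treatment-responsive transcripts from a classification
#'
#' Transcripts differentially expressed between treated and control donors
#' (e.g. Kdm5b-wt vs Kdm5b-ci) at FDR < `fdr_alpha` (strict) are set to
#' `unclassified`, removing expression changes caused by the perturbation
#' itself rather than by reprogramming.
#'
#' @param labels a `memory_labels` data.frame.
#' @param treatment_de a `de_result` covering the labeled transcripts.
#' @param fdr_alpha cutoff, default 0.05.
#' @return The filtered `memory_labels`.
#' @export
exclude_treatment_de <- function(labels, treatment_de, fdr_alpha = 0.05) {
  idx <- match(labels$transcript_id, treatment_de$transcript_id)
  if (anyNA(idx))
    stop2("treatment DE does not cover the labeled transcript universe")
  hit <- treatment_de$fdr[idx] < fdr_alpha
  labels$primary_class[hit] <- "unclassified"
  labels$fc3_flag[hit] <- FALSE
  labels$provenance[hit] <- paste0(labels$provenance[hit],
                                   ";treatment_de_excluded")
  labels
}

#' Per-class counts of a classification
#'
#' @param labels a `memory_labels` data.frame.
#' @return Named integer vector of counts per primary class, plus
#'   `ON_memory_3FC` / `OFF_memory_3FC` flag counts.
#' @export
class_counts <- function(labels) {
  lvls <- c("ON_memory", "OFF_memory", "reprogrammed_down",
            "reprogrammed_up", "reprogrammed", "resistant_other_up",
            "resistant_other_down", "unclassified")
  n <- table(factor(labels$primary_class, levels = lvls))
  out <- c(as.vector(n),
           sum(labels$fc3_flag & labels$primary_class == "ON_memory"),
           sum(labels$fc3_flag & labels$primary_class == "OFF_memory"))
  stats::setNames(as.integer(out), c(lvls, "ON_memory_3FC", "OFF_memory_3FC"))
}

#' Write classification labels and a per-class summary
#'
#' @param labels a `memory_labels` data.frame.
#' @param dir output directory (`labels.tsv`, `summary.json`).
#' @return Invisibly, the directory.
#' @export
write_memory_labels <- function(labels, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(labels, file.path(dir, "labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(class_counts(labels)),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
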