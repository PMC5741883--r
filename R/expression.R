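#' Validate an FPKM expression matrix
#'
#' Gene-by-checkpoint abundance matrix (FPKM). Rows are unigenes, columns
#' the dated sampling checkpoints in calendar order. Values must be
#' non-negative and finite; duplicated gene ids are rejected.
#'
#' @param x numeric matrix (or data frame) with rownames = gene ids.
#' @return the validated numeric matrix, class `expression_matrix`.
#' @export
expression_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(rownames(x)) || any(rownames(x) == "")) {
    abort("expression matrix needs gene ids as rownames",
          "budchill_input_error")
  }
  if (anyDuplicated(rownames(x))) {
    abort(sprintf("duplicated gene id(s): %s",
                  paste(unique(rownames(x)[duplicated(rownames(x))]),
                        collapse = ", ")),
          "budchill_input_error")
  }
  if (any(!is.finite(x))) {
    abort("non-finite FPKM values", "budchill_input_error")
  }
  if (any(x < 0)) abort("negative FPKM values", "budchill_input_error")
  class(x) <- c("expression_matrix", class(x))
  x
}

#' Screen genes with large between-checkpoint differences
#'
#' Fold-change filter with a pseudocount guarding zero expression: a gene
#' is retained iff `(max + pseudocount) / (min + pseudocount) >=
#' fold_threshold` and its peak FPKM reaches `min_peak`. The criterion and
#' its thresholds are deliberately explicit configuration, echoed in every
#' report.
#'
#' @param mat an [expression_matrix()].
#' @param fold_threshold minimum max/min ratio (default 4, must be > 1).
#' @param min_peak minimum peak FPKM (default 1).
#' @param pseudocount added to numerator and denominator (default 0.1,
#'   must be > 0).
#' @return character vector of retained gene ids, with attribute
#'   `criteria` listing the thresholds used.
#' @export
differential_screen <- function(mat, fold_threshold = 4, min_peak = 1,
                                pseudocount = 0.1) {
  mat <- expression_matrix(mat)
  if (fold_threshold <= 1) {
    abort("fold_threshold must be > 1", "budchill_config_error")
  }
  if (pseudocount <= 0) {
    abort("pseudocount must be > 0", "budchill_config_error")
  }
  mx <- apply(mat, 1L, max)
  mn <- apply(mat, 1L, min)
  keep <- (mx + pseudocount) / (mn + pseudocount) >= fold_threshold &
    mx >= min_peak
  structure(rownames(mat)[keep],
            criteria = list(fold_threshold = fold_threshold,
                            min_peak = min_peak,
                            pseudocount = pseudocount))
}

#' Keyword rule set for temperature/photoperiod classification
#'
#' Case-insensitive substring phrases applied to each gene's annotation
#' (description plus homolog name). The defaults follow the standard
#' screening vocabulary for ambient-signal candidate genes: cold/heat
#' stress terms for the temperature class, light-harvesting / photosystem
#' / circadian terms for the photoperiod class.
#'
#' @param temperature_keywords character vector of phrases.
#' @param photoperiod_keywords character vector of phrases.
#' @return list of class `keyword_rules`.
#' @export
keyword_rules <- function(
    temperature_keywords = c(
      "temperature response", "cold response", "cold regulated",
      "cold-regulated", "cold acclimation", "deacclimation",
      "cold-inducible", "heat shock", "low temperature", "freezing",
      "dehydration", "osmotin", "osmotically responsive"),
    photoperiod_keywords = c(
      "light harvesting", "light mediated", "light chain", "photosystem",
      "photosynthesis", "phototropin", "phytochrome", "circadian rhythm",
      "circadian regulation", "circadian")) {
  if (length(temperature_keywords) == 0L ||
      length(photoperiod_keywords) == 0L) {
    abort("keyword lists must be non-empty", "budchill_config_error")
  }
  both <- intersect(tolower(temperature_keywords),
                    tolower(photoperiod_keywords))
  if (length(both)) {
    abort(sprintf("phrase(s) in both keyword lists: %s",
                  paste(both, collapse = ", ")),
          "budchill_config_error")
  }
  structure(list(temperature = tolower(temperature_keywords),
                 photoperiod = tolower(photoperiod_keywords)),
            class = "keyword_rules")
}

check_annotations <- function(annotations) {
  need <- c("gene_id", "homolog_name", "description")
  if (!is.data.frame(annotations) || !all(need %in% names(annotations))) {
    abort(paste("annotations must be a data frame with columns gene_id,",
                "homolog_name, description (homolog_locus optional)"),
          "budchill_input_error")
  }
  if (anyDuplicated(annotations$gene_id)) {
    abort("duplicated gene_id in annotations", "budchill_input_error")
  }
  invisible(annotations)
}

#' Classify annotated genes as temperature- or photoperiod-associated
#'
#' Matches each rule phrase as a case-insensitive substring of the gene's
#' description and homolog name. A gene matching phrases from both lists
#' is classed `temperature` (the temperature list is screened first) with
#' `both = TRUE`.
#'
#' @param annotations data frame with columns `gene_id`, `homolog_name`,
#'   `description` (and optionally `homolog_locus`).
#' @param rules a [keyword_rules()] object.
#' @return data frame with columns `gene_id`, `class` (`temperature`,
#'   `photoperiod` or `none`), `both`, `matched` (matched phrases,
#'   `;`-collapsed).
#' @export
keyword_classify <- function(annotations, rules = keyword_rules()) {
  check_annotations(annotations)
  stopifnot(inherits(rules, "keyword_rules"))
  text <- tolower(paste(annotations$description, annotations$homolog_name))
  hit <- function(phrases, s) phrases[vapply(phrases, grepl, logical(1),
                                             x = s, fixed = TRUE)]
  res <- lapply(text, function(s) {
    th <- hit(rules$temperature, s)
    ph <- hit(rules$photoperiod, s)
    cls <- if (length(th)) "temperature" else if (length(ph)) "photoperiod"
           else "none"
    list(class = cls, both = length(th) > 0 && length(ph) > 0,
         matched = paste(c(th, ph), collapse = ";"))
  })
  data.frame(
    gene_id = annotations$gene_id,
    class = vapply(res, `[[`, character(1), "class"),
    both = vapply(res, `[[`, logical(1), "both"),
    matched = vapply(res, `[[`, character(1), "matched"),
    stringsAsFactors = FALSE
  )
}

#' Count screened genes per homolog
#'
#' Groups a classified gene set by the name of its closest homolog
#' (missing names become `"No Arabidopsis gene name"`) and totals the
#' counts; the total always equals the size of the gene set.
#'
#' @param gene_ids character vector of screened gene ids.
#' @param annotations annotation data frame covering every id.
#' @return data frame with columns `homolog_name`, `n`, sorted by
#'   decreasing count; attribute `total`.
#' @export
summarize_by_homolog <- function(gene_ids, annotations) {
  check_annotations(annotations)
  if (length(gene_ids) == 0L) {
    out <- data.frame(homolog_name = character(0), n = integer(0))
    attr(out, "total") <- 0L
    return(out)
  }
  m <- match(gene_ids, annotations$gene_id)
  if (anyNA(m)) {
    abort(sprintf("unannotated gene id(s): %s",
                  paste(gene_ids[is.na(m)], collapse = ", ")),
          "budchill_lookup_error")
  }
  nm <- annotations$homolog_name[m]
  nm[is.na(nm) | trimws(nm) == ""] <- "No Arabidopsis gene name"
  tab <- table(nm)
  out <- data.frame(homolog_name = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n, out$homolog_name), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total") <- sum(out$n)
  out
}

#' Standardize an expression matrix for heatmap display
#'
#' Per-gene z-scores: subtract the gene's mean across checkpoints, divide
#' by its population (n-denominator) standard deviation, and clip to
#' `[-clip, +clip]` (default 3, the conventional heatmap colour range).
#' Constant genes map to all zeros.
#'
#' @param mat an [expression_matrix()] (or any numeric matrix).
#' @param clip symmetric clipping bound, > 0.
#' @return numeric matrix of standardized values with attribute
#'   `n_clipped` (number of cells clipped).
#' @export
heatmap_normalize <- function(mat, clip = 3) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "double"
  if (!is.numeric(clip) || clip <= 0) {
    abort("clip must be > 0", "budchill_config_error")
  }
  mu <- rowMeans(mat)
  n <- ncol(mat)
  sdp <- sqrt(rowMeans((mat - mu)^2))
  z <- (mat - mu) / ifelse(sdp > 0, sdp, 1)
  z[sdp == 0, ] <- 0
  n_clipped <- sum(abs(z) > clip)
  z <- pmin(pmax(z, -clip), clip)
  attr(z, "n_clipped") <- n_clipped
  z
}

#' Relative expression by the 2^-dCt method
#'
#' `2^-(Ct_target - Ct_reference)`: expression of the target gene relative
#' to the in-sample reference gene, with no calibrator sample (this is
#' 2^-dCt, not 2^-ddCt).
#'
#' @param target_ct,reference_ct cycle-threshold values (finite,
#'   vectorized).
#' @return fold expression relative to the reference.
#' @export
relative_expression <- function(target_ct, reference_ct) {
  if (any(!is.finite(target_ct)) || any(!is.finite(reference_ct))) {
    abort("Ct values must be finite", "budchill_input_error")
  }
  2^-(target_ct - reference_ct)
}

#' Aggregate replicated qPCR readings into a relative expression
#'
#' Technical replicates are averaged within each biological replicate
#' (for target and reference alike), each biological replicate's relative
#' expression is computed against its own reference mean, and the
#' biological replicates are summarized as mean and standard deviation.
#' Technical triplicates whose Ct range exceeds 0.5 cycles are flagged
#' (computed anyway; the flag propagates).
#'
#' @param target_ct,reference_ct numeric matrices with one row per
#'   biological replicate and one column per technical replicate (vectors
#'   are treated as a single biological replicate). `NA` readings are
#'   dropped; a biological replicate with no valid reading in either gene
#'   is dropped.
#' @param flag_range technical-range threshold in cycles (default 0.5).
#' @return list of class `qpcr_result`: `mean`, `sd` (`NA` with a single
#'   biological replicate), `per_replicate`, `flagged` (logical per
#'   biological replicate).
#' @export
aggregate_qpcr <- function(target_ct, reference_ct, flag_range = 0.5) {
  as_mat <- function(x) {
    if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  }
  tg <- as_mat(target_ct)
  rf <- as_mat(reference_ct)
  if (nrow(tg) != nrow(rf)) {
    abort("target and reference must have the same biological replicates",
          "budchill_input_error")
  }
  ok_val <- function(m) is.finite(m) & m > 0 & m < 45
  if (any(!ok_val(tg[!is.na(tg)])) || any(!ok_val(rf[!is.na(rf)]))) {
    abort("Ct readings must lie in (0, 45)", "budchill_input_error")
  }
  rows <- lapply(seq_len(nrow(tg)), function(i) {
    t_i <- tg[i, ][!is.na(tg[i, ])]
    r_i <- rf[i, ][!is.na(rf[i, ])]
    if (length(t_i) == 0L || length(r_i) == 0L) return(NULL)
    list(rel = relative_expression(mean(t_i), mean(r_i)),
         flag = (length(t_i) > 1 && diff(range(t_i)) > flag_range) ||
                (length(r_i) > 1 && diff(range(r_i)) > flag_range))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    abort("all qPCR readings missing", "budchill_input_error")
  }
  rel <- vapply(rows, `[[`, numeric(1), "rel")
  structure(list(mean = mean(rel),
                 sd = if (length(rel) > 1) stats::sd(rel) else NA_real_,
                 per_replicate = rel,
                 flagged = vapply(rows, `[[`, logical(1), "flag")),
            class = "qpcr_result")
}

#' @export
print.qpcr_result <- function(x, ...) {
  cat(sprintf("Relative expression (2^-dCt): %.4g +/- %s over %d biological replicate(s)%s\n",
              x$mean, if (is.na(x$sd)) "NA" else sprintf("%.4g", x$sd),
              length(x$per_replicate),
              if (any(x$flagged)) sprintf(" [%d flagged triplicate(s)]",
                                          sum(x$flagged)) else ""))
  invisible(x)
}

#' Summarize a long-format qPCR table
#'
#' Applies [aggregate_qpcr()] to every target gene x checkpoint of a
#' long-format table with columns `gene_id`, `date`, `biological`,
#' `technical`, `ct`, `is_reference`; reference rows (any gene with
#' `is_reference = TRUE`) supply the per-sample reference Ct.
#'
#' @param qpcr long-format qPCR data frame.
#' @param flag_range see [aggregate_qpcr()].
#' @return data frame with columns `gene_id`, `date`, `mean`, `sd`,
#'   `n_bio`, `n_flagged`.
#' @export
summarize_qpcr <- function(qpcr, flag_range = 0.5) {
  need <- c("gene_id", "date", "biological", "technical", "ct",
            "is_reference")
  if (!is.data.frame(qpcr) || !all(need %in% names(qpcr))) {
    abort(sprintf("qPCR table needs columns %s",
                  paste(need, collapse = ", ")),
          "budchill_input_error")
  }
  refs <- qpcr[qpcr$is_reference, , drop = FALSE]
  if (nrow(refs) == 0L) {
    abort("no reference-gene rows (is_reference = TRUE)",
          "budchill_input_error")
  }
  targets <- qpcr[!qpcr$is_reference, , drop = FALSE]
  keys <- unique(targets[, c("gene_id", "date")])
  ct_matrix <- function(d) {
    bio <- sort(unique(d$biological))
    t(vapply(bio, function(b) {
      v <- d$ct[d$biological == b][order(d$technical[d$biological == b])]
      length(v) <- max(table(d$biological))
      v
    }, numeric(max(table(d$biological)))))
  }
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    g <- keys$gene_id[i]
    dt <- keys$date[i]
    tg <- targets[targets$gene_id == g & targets$date == dt, ]
    rf <- refs[refs$date == dt, ]
    if (nrow(rf) == 0L) {
      abort(sprintf("no reference readings for checkpoint %s", dt),
            "budchill_input_error")
    }
    res <- aggregate_qpcr(ct_matrix(tg), ct_matrix(rf),
                          flag_range = flag_range)
    data.frame(gene_id = g, date = dt, mean = res$mean, sd = res$sd,
               n_bio = length(res$per_replicate),
               n_flagged = sum(res$flagged))
  })
  do.call(rbind, rows)
}

#' Read an FPKM expression matrix from delimited text
#'
#' First column gene ids, remaining columns dated checkpoints.
#'
#' @param path file path.
#' @param sep separator; `NULL` auto-detects comma vs tab.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, sep = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), "budchill_io_error")
  }
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                           check.names = FALSE)
  expression_matrix(as.matrix(tab))
}

#' Read an annotation table from delimited text
#'
#' @param path file path.
#' @param mapping named list mapping `gene_id`, `homolog_locus`,
#'   `homolog_name`, `description` to the file's column names.
#' @param sep separator; `NULL` auto-detects.
#' @return annotation data frame with canonical column names; rows with
#'   empty homolog or description fields are kept and counted in the
#'   `n_incomplete` attribute.
#' @export
read_annotations <- function(path,
                             mapping = list(gene_id = "gene_id",
                                            homolog_locus = "homolog_locus",
                                            homolog_name = "homolog_name",
                                            description = "description"),
                             sep = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), "budchill_io_error")
  }
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"")
  out <- data.frame(gene_id = tab[[mapping$gene_id]],
                    stringsAsFactors = FALSE)
  for (f in c("homolog_locus", "homolog_name", "description")) {
    nm <- mapping[[f]]
    out[[f]] <- if (!is.null(nm) && nm %in% names(tab)) {
      as.character(tab[[nm]])
    } else {
      NA_character_
    }
  }
  check_annotations(out)
  attr(out, "n_incomplete") <-
    sum(!stats::complete.cases(out) |
          rowSums(out == "" | is.na(out)) > 0)
  out
}
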