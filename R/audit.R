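# The audit table: per-entry record assembly, curation filters,
# membrane/soluble subset classification, and CSV serialization.

# fixed audit-table schema: column name -> storage type
.audit_schema <- c(
  entry_id = "character", year = "integer", resolution = "numeric",
  sg_symbol = "character",
  cell_a = "numeric", cell_b = "numeric", cell_c = "numeric",
  cell_alpha = "numeric", cell_beta = "numeric", cell_gamma = "numeric",
  temperature = "numeric", het_ids = "character", keywords = "character",
  solvent_pct = "numeric", matthews = "numeric",
  n_contacts = "integer", n_atoms_total = "integer",
  contacts_ratio = "numeric",
  aniso_b_amp = "numeric", aniso_b_int = "numeric",
  wilson_b_amp = "numeric", wilson_b_int = "numeric",
  ratio_amp = "numeric", ratio_int = "numeric",
  axis_limit_1 = "numeric", axis_limit_2 = "numeric",
  axis_limit_3 = "numeric", delta_res = "numeric",
  pct_rejected = "numeric",
  ss_helix = "numeric", ss_strand = "numeric", ss_turn = "numeric",
  ss_coil = "numeric", subset_labels = "character"
)

.empty_records <- function(n) {
  cols <- lapply(.audit_schema, function(tp) {
    switch(tp, character = rep(NA_character_, n),
           integer = rep(NA_integer_, n), rep(NA_real_, n))
  })
  as.data.frame(cols, stringsAsFactors = FALSE)
}

#' Assemble one audit record
#'
#' Flattens header, anisotropy and packing results into one audit-table
#' row. The header's solvent content takes precedence when present;
#' otherwise the Matthews-derived value from packing is used. Absent
#' metrics stay `NA` and propagate as empty CSV fields.
#'
#' @param header An `entry_header` (see [parse_pdb_header()]).
#' @param aniso An `aniso_result` ([anisotropy_audit()]) or NULL.
#' @param packing A `packing_result` ([packing_metrics()]) or NULL.
#' @param ss Optional named list/vector of externally computed secondary
#'   structure percentages: `helix`, `strand`, `turn`, `coil`.
#' @return One-row data.frame in the audit-table schema.
#' @export
build_record <- function(header, aniso = NULL, packing = NULL, ss = NULL) {
  stopifnot(inherits(header, "entry_header"))
  r <- .empty_records(1)
  r$entry_id <- header$entry_id
  r$year <- header$year
  r$resolution <- header$resolution
  r$sg_symbol <- header$sg_symbol
  if (!is.null(header$cell)) {
    r$cell_a <- header$cell$a; r$cell_b <- header$cell$b
    r$cell_c <- header$cell$c; r$cell_alpha <- header$cell$alpha
    r$cell_beta <- header$cell$beta; r$cell_gamma <- header$cell$gamma
  }
  r$temperature <- header$temperature
  if (length(header$het_ids)) r$het_ids <- paste(header$het_ids, collapse = ";")
  if (length(header$keywords)) r$keywords <- paste(header$keywords, collapse = ";")
  # header solvent content wins; computed value is the fallback
  r$solvent_pct <- if (!is.na(header$solvent_content)) header$solvent_content
                   else if (!is.null(packing)) packing$solvent_pct
                   else NA_real_
  if (!is.null(packing)) {
    r$matthews <- packing$matthews
    r$n_contacts <- packing$n_contacts
    r$n_atoms_total <- packing$n_atoms_total
    r$contacts_ratio <- packing$contacts_ratio
  }
  if (!is.null(aniso)) {
    r$aniso_b_amp <- aniso$aniso_b_amp
    r$aniso_b_int <- aniso$aniso_b_int
    r$wilson_b_amp <- aniso$wilson_b_amp
    r$wilson_b_int <- aniso$wilson_b_int
    r$ratio_amp <- aniso$ratio_amp
    r$ratio_int <- aniso$ratio_int
    r$axis_limit_1 <- aniso$axis_limits[1]
    r$axis_limit_2 <- aniso$axis_limits[2]
    r$axis_limit_3 <- aniso$axis_limits[3]
    r$delta_res <- aniso$delta_res
    r$pct_rejected <- aniso$pct_rejected
  }
  if (!is.null(ss)) {
    ss <- as.list(ss)
    for (k in c("helix", "strand", "turn", "coil")) {
      if (!is.null(ss[[k]])) r[[paste0("ss_", k)]] <- as.numeric(ss[[k]])
    }
  }
  r
}

#' Curate audit records
#'
#' Applies the four curation filters: records are kept when the revision
#' year is 2006 or later (strictly after 2005), resolution is at most
#' 5.0 Angstrom, the amplitude-based delta-B does not exceed 150 A^2, and
#' the crystal-contacts ratio does not exceed 1. The resolution, delta-B
#' and ratio boundaries are inclusive on the keep side. Records with an
#' absent delta-B or contacts ratio are not dropped by those rules (the
#' filters apply to computed values, not to missingness). Each dropped
#' record carries its first failing rule, checked in the order year,
#' resolution, aniso_b, contacts_ratio.
#'
#' @param records data.frame of audit records; `year` and `resolution`
#'   must be populated.
#' @param min_year,max_res,max_aniso_b,max_contacts_ratio Filter bounds;
#'   defaults 2006, 5.0, 150, 1.0.
#' @return List with `kept` (data.frame) and `dropped` (data.frame with an
#'   extra `drop_reason` column). Together they partition the input.
#' @export
curate <- function(records, min_year = 2006, max_res = 5.0,
                   max_aniso_b = 150, max_contacts_ratio = 1.0) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) {
    return(list(kept = records,
                dropped = cbind(records, drop_reason = character(0))))
  }
  if (any(is.na(records$year)) || any(is.na(records$resolution))) {
    stop("curation requires year and resolution on every record")
  }
  reason <- rep(NA_character_, nrow(records))
  chk <- function(cond, why) {
    hit <- is.na(reason) & cond
    reason[hit] <<- why
  }
  chk(records$year < min_year, "year")
  chk(records$resolution > max_res, "resolution")
  chk(!is.na(records$aniso_b_amp) & records$aniso_b_amp > max_aniso_b,
      "aniso_b")
  chk(!is.na(records$contacts_ratio) &
        records$contacts_ratio > max_contacts_ratio, "contacts_ratio")
  kept <- records[is.na(reason), , drop = FALSE]
  dropped <- records[!is.na(reason), , drop = FALSE]
  dropped$drop_reason <- reason[!is.na(reason)]
  row.names(kept) <- NULL; row.names(dropped) <- NULL
  list(kept = kept, dropped = dropped)
}

# default keyword/het-id markers for lipidic-cubic-phase crystallization;
# monoolein-class lipid het codes included
.default_lcp_keywords <- c("LIPIDIC CUBIC PHASE", "LCP", "MESO",
                           "OLC", "OLB", "OLA", "MPG")

#' Membrane/soluble subset labels for one record
#'
#' Assigns exactly one of `soluble` / `membrane` plus all applicable
#' membrane sub-labels: fold (`alpha_helical`, `beta_barrel`,
#' `monotopic`), crystallization (`detergent`, `lcp`, `bicelle`),
#' function (`atpase`, `electron_transfer`, `channel`, `receptor`,
#' `transporter`) and topology (`embedded`, `extramembranous_domains`).
#' Entries absent from the annotation table default to `soluble`. When
#' the crystallization annotation is `unknown`, `lcp` may still be
#' inferred from the entry's keywords and het ids via `lcp_keywords`.
#'
#' @param record One-row audit data.frame.
#' @param annot Annotation table from [read_annotation()], or NULL.
#' @param lcp_keywords Markers for LCP inference (case-insensitive).
#' @return Character vector of subset labels.
#' @export
classify_subsets <- function(record, annot = NULL,
                             lcp_keywords = .default_lcp_keywords) {
  stopifnot(is.data.frame(record), nrow(record) == 1)
  a <- if (!is.null(annot)) annot[annot$entry_id == record$entry_id, ]
       else NULL
  if (is.null(a) || nrow(a) == 0) return("soluble")
  a <- a[1, ]
  is_mem <- isTRUE(as.logical(a$is_membrane))
  if (!is_mem) {
    if (!is.na(a$fold) && a$fold != "none") {
      stop("contradictory annotation for ", record$entry_id,
           ": soluble entry with membrane fold '", a$fold, "'")
    }
    return("soluble")
  }
  labels <- "membrane"
  if (!is.na(a$fold) && a$fold %in% c("alpha_helical", "beta_barrel",
                                      "monotopic")) {
    labels <- c(labels, a$fold)
  }
  cryst <- if (is.na(a$crystallization)) "unknown" else a$crystallization
  if (cryst %in% c("detergent", "lcp", "bicelle")) {
    labels <- c(labels, cryst)
  } else if (cryst == "unknown") {
    text_pool <- toupper(c(
      strsplit(if (is.na(record$keywords)) "" else record$keywords, ";")[[1]],
      strsplit(if (is.na(record$het_ids)) "" else record$het_ids, ";")[[1]]))
    hit <- any(vapply(toupper(lcp_keywords), function(kw) {
      any(text_pool == kw) || any(grepl(kw, text_pool, fixed = TRUE) &
                                    nchar(kw) > 4)
    }, logical(1)))
    if (hit) labels <- c(labels, "lcp")
  }
  if (!is.na(a$fn) && a$fn %in% c("atpase", "electron_transfer", "channel",
                                  "receptor", "transporter")) {
    labels <- c(labels, a$fn)
  }
  if (!is.na(a$topology) &&
      a$topology %in% c("embedded", "extramembranous_domains")) {
    labels <- c(labels, a$topology)
  }
  labels
}

#' Apply subset classification to a whole audit table
#'
#' @param records Audit data.frame.
#' @param annot Annotation table from [read_annotation()], or NULL.
#' @param lcp_keywords Markers for LCP inference.
#' @return The records with the `subset_labels` column filled
#'   (semicolon-joined).
#' @export
assign_subsets <- function(records, annot = NULL,
                           lcp_keywords = .default_lcp_keywords) {
  records$subset_labels <- vapply(seq_len(nrow(records)), function(k) {
    paste(classify_subsets(records[k, , drop = FALSE], annot, lcp_keywords),
          collapse = ";")
  }, "")
  records
}

#' Read a membrane-annotation table
#'
#' Tab-separated text with a header line and columns `entry_id`,
#' `is_membrane` (TRUE/FALSE), `fold` (alpha_helical / beta_barrel /
#' monotopic / none), `crystallization` (detergent / lcp / bicelle /
#' unknown), `function` (atpase / electron_transfer / channel / receptor /
#' transporter / other) and `topology` (embedded /
#' extramembranous_domains / unknown).
#'
#' @param path Path to the TSV file.
#' @return data.frame with the `function` column renamed to `fn`.
#' @export
read_annotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  need <- c("entry_id", "is_membrane", "fold", "crystallization",
            "function", "topology")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("annotation table lacks column(s): ", paste(missing, collapse = ", "))
  }
  names(tab)[names(tab) == "function"] <- "fn"
  vocab <- list(fold = c("alpha_helical", "beta_barrel", "monotopic", "none"),
                crystallization = c("detergent", "lcp", "bicelle", "unknown"),
                fn = c("atpase", "electron_transfer", "channel", "receptor",
                       "transporter", "other"),
                topology = c("embedded", "extramembranous_domains", "unknown"))
  for (col in names(vocab)) {
    bad <- setdiff(stats::na.omit(unique(tab[[col]])), vocab[[col]])
    if (length(bad)) {
      stop("annotation column '", col, "' has values outside its vocabulary: ",
           paste(bad, collapse = ", "))
    }
  }
  tab
}

#' Write the audit table as CSV
#'
#' One row per record, sorted by entry id, fixed header row. Absent values
#' are written as empty fields, never 0.
#'
#' @param records Audit data.frame.
#' @param path Output CSV path.
#' @return The sorted records, invisibly.
#' @export
write_audit_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) stop("no records to write")
  records <- records[order(records$entry_id), , drop = FALSE]
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(records)
}

#' Read an audit table written by [write_audit_table()]
#'
#' @param path CSV path.
#' @return data.frame with schema column types restored; empty fields
#'   become `NA`.
#' @export
read_audit_table <- function(path) {
  first <- strsplit(readLines(path, n = 1), ",")[[1]]
  cols <- gsub('"', "", first)
  classes <- ifelse(cols %in% names(.audit_schema),
                    .audit_schema[cols], "character")
  # planted/bookkeeping columns keep sensible types
  classes[cols == "planted_verdict" | cols == "planted_reason" |
            cols == "drop_reason"] <- "character"
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = unname(classes), na.strings = "")
  tab
}
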