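# Per-subject aggregation of every analysis stage, ordered by metabolic
# severity, plus deterministic TSV/JSON rendering.

.zygosity_mark <- c(HET = "het", HOM_ALT = "hom", HEMI_ALT = "hemi")

# natural sort order for subject ids: numeric when all-numeric, else lexical
.id_order_key <- function(ids) {
  num <- suppressWarnings(as.numeric(ids))
  if (anyNA(num)) ids else num
}

#' Build per-subject variant summaries
#'
#' Aggregates catalog hits, the terminal oxidoreductase and shared cascade
#' sets, and the interactome scan into one summary per subject. Categories
#' are `<GENE>_KNOWN` for catalog hits (one per catalog gene),
#' `OXIDOREDUCTASE`, `INTERACTOME` and `RARE_SHARED`; a shared variant
#' contributes one entry to every sharing subject. Summaries are ordered by
#' ascending oxidation ratio, ties broken by subject id.
#'
#' @param profiles A [metabolic_profiles()] data frame covering every subject.
#' @param catalog_hits A `catalog_hits` data frame from
#'   [lookup_known_variants()].
#' @param cascade_report A `cascade_report` from [run_cascade()].
#' @param interactome_hits Character vector of keys from
#'   [interactome_variant_scan()].
#' @param matrix The [genotype_matrix()] the report was built from (supplies
#'   carrier zygosities for the cascade and interactome variants).
#' @return A `subject_summaries` data frame with columns `subject_id`,
#'   `ratio`, one `n_<category>` count column per category seen, and `total`;
#'   the per-variant rows (subject, category, variant id, zygosity mark) are
#'   attached as `attr(, "entries")`.
#' @export
build_subject_summaries <- function(profiles, catalog_hits, cascade_report,
                                    interactome_hits, matrix) {
  entries <- list(data.frame(subject_id = character(0), category = character(0),
                             variant_id = character(0), mark = character(0),
                             stringsAsFactors = FALSE))
  add <- function(subject_id, category, variant_id, zygosity) {
    entries[[length(entries) + 1L]] <<- data.frame(
      subject_id = subject_id, category = category, variant_id = variant_id,
      mark = unname(.zygosity_mark[zygosity]), stringsAsFactors = FALSE)
  }
  if (nrow(catalog_hits))
    add(catalog_hits$subject_id,
        paste0(toupper(catalog_hits$gene), "_KNOWN"),
        catalog_hits$rsid, catalog_hits$zygosity)
  carriers_of <- function(key) {
    zy <- matrix$geno[, key]
    which_c <- zy %in% .carrier_states
    list(ids = matrix$subjects$id[which_c], zy = unname(zy[which_c]))
  }
  for (k in cascade_terminal(cascade_report, "OXIDOREDUCTASE")) {
    cr <- carriers_of(k)
    if (length(cr$ids)) add(cr$ids, "OXIDOREDUCTASE", k, cr$zy)
  }
  for (k in interactome_hits) {
    cr <- carriers_of(k)
    if (length(cr$ids)) add(cr$ids, "INTERACTOME", k, cr$zy)
  }
  sharing <- cascade_report$sharing
  for (k in names(sharing)) {
    ids <- sharing[[k]]
    add(ids, "RARE_SHARED", k, unname(matrix$geno[ids, k]))
  }
  entries <- do.call(rbind, entries)
  stray <- setdiff(unique(entries$subject_id), profiles$subject_id)
  if (length(stray))
    stop("subject(s) with variants but no metabolic profile: ",
         paste(stray, collapse = ", "))

  cats <- sort(unique(entries$category))
  out <- data.frame(subject_id = profiles$subject_id, ratio = profiles$ratio,
                    stringsAsFactors = FALSE)
  for (cc in cats)
    out[[paste0("n_", tolower(cc))]] <- vapply(out$subject_id, function(id)
      sum(entries$subject_id == id & entries$category == cc), integer(1))
  out$total <- vapply(out$subject_id, function(id)
    sum(entries$subject_id == id), integer(1))
  out <- out[order(out$ratio, .id_order_key(out$subject_id)), , drop = FALSE]
  rownames(out) <- NULL
  entries <- entries[order(match(entries$subject_id, out$subject_id),
                           entries$category, entries$variant_id), , drop = FALSE]
  rownames(entries) <- NULL
  attr(out, "entries") <- entries
  class(out) <- c("subject_summaries", "data.frame")
  out
}

#' Render summary and cascade tables to files
#'
#' Writes deterministic, byte-stable TSV and/or JSON renderings: identical
#' inputs always produce identical bytes (stable ordering, ratios fixed to
#' two decimals). TSV output comprises `subject_summaries.tsv`,
#' `variant_entries.tsv` and `cascade_steps.tsv`; JSON output is a single
#' `results.json` mirroring the same content.
#'
#' @param summaries A `subject_summaries` data frame.
#' @param cascade_report A `cascade_report`.
#' @param dir Output directory (created if needed).
#' @param formats Any of `"tsv"`, `"json"`.
#' @return Named character vector of the paths written, invisibly.
#' @export
render_tables <- function(summaries, cascade_report, dir,
                          formats = c("tsv", "json")) {
  formats <- match.arg(formats, several.ok = TRUE)
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || !dir.exists(dir)) stop("cannot create output directory: ", dir)
  entries <- attr(summaries, "entries")
  paths <- character(0)

  fmt_row <- function(...) paste(..., sep = "\t", collapse = "\t")
  if ("tsv" %in% formats) {
    p <- file.path(dir, "subject_summaries.tsv")
    count_cols <- setdiff(names(summaries), c("subject_id", "ratio", "total"))
    lines <- c(fmt_row(c("subject_id", "ratio", count_cols, "total")))
    for (i in seq_len(nrow(summaries)))
      lines <- c(lines, fmt_row(c(
        summaries$subject_id[i], sprintf("%.2f", summaries$ratio[i]),
        vapply(count_cols, function(cc) as.character(summaries[[cc]][i]),
               character(1)),
        as.character(summaries$total[i]))))
    writeLines(lines, p)
    paths["subject_summaries"] <- p

    p <- file.path(dir, "variant_entries.tsv")
    lines <- c("subject_id\tcategory\tvariant_id\tmark")
    if (!is.null(entries) && nrow(entries))
      lines <- c(lines, vapply(seq_len(nrow(entries)), function(i)
        fmt_row(c(entries$subject_id[i], entries$category[i],
                  entries$variant_id[i], entries$mark[i])), character(1)))
    writeLines(lines, p)
    paths["variant_entries"] <- p

    p <- file.path(dir, "cascade_steps.tsv")
    s <- cascade_report$steps
    lines <- c("branch\tlabel\tsnp_count\tindel_count",
               vapply(seq_len(nrow(s)), function(i)
                 fmt_row(c(s$branch[i], s$label[i],
                           as.character(s$snp_count[i]),
                           as.character(s$indel_count[i]))), character(1)))
    writeLines(lines, p)
    paths["cascade_steps"] <- p
  }

  if ("json" %in% formats) {
    p <- file.path(dir, "results.json")
    payload <- list(
      subjects = lapply(seq_len(nrow(summaries)), function(i) {
        row <- summaries[i, , drop = FALSE]
        sid <- row$subject_id
        ent <- if (is.null(entries)) NULL
               else entries[entries$subject_id == sid, , drop = FALSE]
        list(
          subject_id = sid,
          ratio = round(row$ratio, 2),
          total = row$total,
          variants = if (is.null(ent) || !nrow(ent)) list()
                     else lapply(seq_len(nrow(ent)), function(j)
                       list(category = ent$category[j],
                            variant_id = ent$variant_id[j],
                            mark = ent$mark[j]))
        )
      }),
      cascade = lapply(seq_len(nrow(cascade_report$steps)), function(i) {
        s <- cascade_report$steps
        list(branch = s$branch[i], label = s$label[i],
             snp_count = s$snp_count[i], indel_count = s$indel_count[i])
      })
    )
    writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA), p)
    paths["json"] <- p
  }
  invisible(paths)
}
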