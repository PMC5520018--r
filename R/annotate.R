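#' CpG creation and disruption by a SNP's alleles
#'
#' Reading 5'-3', allele X creates a CpG site iff the left flanking base is C
#' and X is G, or X is C and the right flanking base is G. An allele breaks a
#' CpG iff the other allele creates one and it does not.
#'
#' @param left_base,right_base flanking bases (A/C/G/T).
#' @param alleles character vector of the two distinct alleles.
#' @return data.frame allele/creates_cpg/breaks_cpg.
#' @export
cpg_flags <- function(left_base, alleles, right_base) {
  bases <- c("A", "C", "G", "T")
  if (!left_base %in% bases || !right_base %in% bases ||
      !all(alleles %in% bases))
    stop("ambiguity codes are not supported; bases must be A/C/G/T")
  stopifnot(length(alleles) == 2, alleles[1] != alleles[2])
  creates <- (left_base == "C" & alleles == "G") |
    (alleles == "C" & right_base == "G")
  breaks <- rev(creates) & !creates
  data.frame(allele = alleles, creates_cpg = creates, breaks_cpg = breaks,
             stringsAsFactors = FALSE)
}

# scoring rubric: one entry per evidence category; within a category only the
# highest-weight matching state counts (B-LCL promoter/enhancer combined,
# 15-cell-type TSS/enhancer combined, DNase/bound-protein occupancy combined),
# which caps the total at the advertised 15
score_rubric <- function() {
  list(
    eqtl = function(r) if (isTRUE(r$eqtl)) 3L else 0L,
    nonsense_or_missense = function(r)
      if (isTRUE(r$nonsense_or_missense)) 3L else 0L,
    blcl = function(r) {
      if (identical(r$blcl_promoter, "active")) 3L
      else if (identical(r$blcl_promoter, "weak") ||
               identical(r$blcl_enhancer, "weak")) 1L
      else 0L
    },
    cell15 = function(r) {
      if (identical(r$tss_15, "active_or_poised")) 3L
      else if (identical(r$tss_15, "upstream_flanking")) 2L
      else if (identical(r$tss_15, "weak") ||
               identical(r$enhancer_15, "any")) 1L
      else 0L
    },
    conserved = function(r) if (isTRUE(r$conserved)) 2L else 0L,
    occupancy = function(r)
      if (isTRUE(r$dnase_5) || isTRUE(r$bound_protein)) 1L else 0L)
}

#' Biological annotation score (0-15)
#'
#' Weighted sum over annotation categories: eQTL 3, nonsense/missense 3,
#' B-LCL regulatory state (active promoter 3; weak promoter or weak enhancer
#' 1), 15-immune-cell-type chromatin state (active/poised TSS 3, upstream
#' flanking TSS 2, weak TSS or any enhancer 1), conserved region 2, and
#' biochemical occupancy (DNase hypersensitivity in any of 5 cell lines, or
#' any bound protein) 1. Within each combined category only the
#' highest-weight state counts, so the maximum attainable score is 15.
#'
#' @param record one-row data.frame or list with the annotation fields (see
#'   [simulate_annotations()]); absent fields score 0.
#' @return integer score in `[0, 15]`.
#' @export
biological_score <- function(record) {
  record <- as.list(record)
  lev <- list(blcl_promoter = c("none", "weak", "active"),
              blcl_enhancer = c("none", "weak"),
              tss_15 = c("none", "weak", "upstream_flanking",
                         "active_or_poised"),
              enhancer_15 = c("none", "any"))
  for (f in names(lev)) {
    if (!is.null(record[[f]]) && !record[[f]] %in% lev[[f]])
      stop("invalid level '", record[[f]], "' for ", f)
  }
  sum(vapply(score_rubric(), function(rule) rule(record), integer(1)))
}

#' Score a table of annotation records
#'
#' @param annotations data.frame, one row per SNP.
#' @return the input with a `biological_score` column appended.
#' @export
biological_score_table <- function(annotations) {
  annotations$biological_score <- vapply(seq_len(nrow(annotations)),
                                         function(i)
                                           biological_score(annotations[i, ]),
                                         integer(1))
  annotations
}

#' Join eQTL records to target SNPs through LD proxies
#'
#' Proxies with r^2 >= `r2_min` to a target are attached; among multiple
#' proxies for the same target SNP and gene, only the record with the lowest
#' eQTL P is retained (tissue preserved).
#'
#' @param targets character vector of target SNP ids.
#' @param ld_pairs data.frame snp_id/proxy_id/r2 (a SNP is its own proxy with
#'   r2 = 1 implicitly).
#' @param eqtl data.frame snp_id/gene/tissue/p (snp_id may be a proxy id).
#' @param r2_min proxy threshold.
#' @return data.frame snp_id/gene/tissue/p/proxy_id/r2, one row per
#'   target-gene pair.
#' @export
eqtl_proxy_join <- function(targets, ld_pairs, eqtl, r2_min = 0.5) {
  empty <- data.frame(snp_id = character(), gene = character(),
                      tissue = character(), p = numeric(),
                      proxy_id = character(), r2 = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(eqtl)) return(empty)
  self <- data.frame(snp_id = targets, proxy_id = targets,
                     r2 = rep(1, length(targets)))
  links <- rbind(self, ld_pairs[, c("snp_id", "proxy_id", "r2")])
  links <- links[links$snp_id %in% targets & links$r2 >= r2_min, ,
                 drop = FALSE]
  hit <- merge(links, eqtl, by.x = "proxy_id", by.y = "snp_id")
  if (!nrow(hit)) return(empty)
  hit <- hit[order(hit$p), ]
  hit <- hit[!duplicated(hit[, c("snp_id", "gene")]), ]
  rownames(hit) <- NULL
  hit[, c("snp_id", "gene", "tissue", "p", "proxy_id", "r2")]
}
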