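#' Parent-of-origin assignment from KIR types
#'
#' Compares a child haplotype's full KIR type vector with each parental
#' haplotype's vector and requires an exact match over all loci.  The child
#' haplotype is assigned paternal or maternal when it matches haplotypes of
#' exactly one parent, `ambiguous` when it matches haplotypes of both
#' parents, and `unassigned` when it matches none.
#'
#' @param child Named character vector of KIR types for one haplotype.
#' @param father,mother Matrix or data frame of parental haplotype type
#'   vectors (rows = haplotypes, columns = loci); `NULL` when the parent is
#'   untyped.
#' @return List with `origin` (`paternal`, `maternal`, `ambiguous`,
#'   `unassigned`) and `within_parent_ambiguous` (matched both haplotypes of
#'   the assigned parent).
#' @export
match_by_kir <- function(child, father = NULL, mother = NULL) {
  .match_origin(child, father, mother, function(a, b) {
    if (!identical(sort(names(a)), sort(names(b))))
      stop("KIR locus sets differ between child and parent")
    all(a[names(b)] == b)
  })
}

#' Parent-of-origin assignment from SNP haplotypes
#'
#' A parental haplotype matches the child haplotype when their Hamming
#' distance is strictly below `max_mismatch` (fewer than 20 mismatches by
#' default), tolerating residual phasing or genotyping error.  Assignment
#' semantics are as in [match_by_kir()].
#'
#' @param child Integer 0/1 vector of phased alleles for one haplotype.
#' @param father,mother Matrix of parental haplotypes (rows = haplotypes)
#'   over the identical SNP set; `NULL` when the parent has no SNP data.
#' @param max_mismatch Strict mismatch bound (default 20).
#' @return As [match_by_kir()].
#' @export
match_by_snp <- function(child, father = NULL, mother = NULL,
                         max_mismatch = 20L) {
  .match_origin(child, father, mother, function(a, b) {
    if (length(a) != length(b))
      stop("haplotype lengths differ (", length(a), " vs ", length(b), ")")
    sum(a != b, na.rm = TRUE) < max_mismatch
  })
}

.match_origin <- function(child, father, mother, matches) {
  side_hits <- function(par) {
    if (is.null(par)) return(0L)
    par <- as.matrix(par)
    sum(vapply(seq_len(nrow(par)), function(i) matches(child, par[i, ]),
               logical(1L)))
  }
  fh <- side_hits(father)
  mh <- side_hits(mother)
  origin <- if (fh > 0L && mh > 0L) "ambiguous"
            else if (fh > 0L) "paternal"
            else if (mh > 0L) "maternal"
            else "unassigned"
  list(origin = origin,
       within_parent_ambiguous = (fh > 1L) || (mh > 1L))
}

#' Merge KIR- and SNP-based parent-of-origin assignments
#'
#' The two evidence sources must be reconcilable: agreement keeps the shared
#' origin with evidence `both`; when one source is `unassigned` the other
#' wins; any disagreement or ambiguity excludes the haplotype (origin
#' `ambiguous`, evidence `conflict`).
#'
#' @param kir,snp Origin strings (or the lists returned by [match_by_kir()] /
#'   [match_by_snp()]).
#' @return List with `origin` and `evidence` (`kir`, `snp`, `both`,
#'   `conflict`, or `none`).
#' @export
merge_assignments <- function(kir, snp) {
  k <- if (is.list(kir)) kir$origin else kir
  s <- if (is.list(snp)) snp$origin else snp
  if (k == "ambiguous" || s == "ambiguous")
    return(list(origin = "ambiguous", evidence = "conflict"))
  if (k == "unassigned" && s == "unassigned")
    return(list(origin = "unassigned", evidence = "none"))
  if (k == "unassigned") return(list(origin = s, evidence = "snp"))
  if (s == "unassigned") return(list(origin = k, evidence = "kir"))
  if (k == s) return(list(origin = k, evidence = "both"))
  list(origin = "ambiguous", evidence = "conflict")
}

#' Select unrelated haplotypes within one family
#'
#' Implements the relatedness-pruning rule used to build the reference
#' panel: with both parents present only the parental haplotypes are kept
#' (children are copies by descent); with one parent, that parent's
#' haplotypes are kept plus any haplotype identified among the offspring
#' that is not present in the parent, deduplicated among the offspring; with
#' no parents, distinct offspring haplotypes are kept after within-family
#' deduplication.  Offspring haplotypes with conflicting or ambiguous
#' parent-of-origin evidence are excluded.
#'
#' @param family List with `father_haps` and `mother_haps` (character vectors
#'   of typed parental haplotype ids, `NULL` for an untyped parent),
#'   `offspring` (data frame: `haplotype_id`, `origin`, `evidence`), and
#'   `hap_key` (named character vector giving each offspring haplotype's
#'   deduplication key: its exact KIR + SNP content).
#' @return Character vector of kept haplotype ids.
#' @export
select_unrelated <- function(family) {
  fh <- family$father_haps
  mh <- family$mother_haps
  both <- !is.null(fh) && !is.null(mh)
  none <- is.null(fh) && is.null(mh)
  if (both) return(c(fh, mh))

  off <- family$offspring
  if (is.null(off) || nrow(off) == 0L) return(c(fh, mh))
  keep_par <- c(fh, mh)
  # candidates: offspring haplotypes not present in the typed parent (or all,
  # when no parent is typed); ambiguous/conflict evidence always excludes
  cand <- if (none) off$haplotype_id
          else off$haplotype_id[off$origin == "unassigned"]
  cand <- setdiff(cand, off$haplotype_id[off$origin == "ambiguous"])
  keys <- family$hap_key[cand]
  cand <- cand[!duplicated(keys)]
  c(keep_par, cand)
}

#' Build an unrelated-haplotype reference panel from family data
#'
#' Reconstructs the panel-construction procedure for family cohorts: the
#' parent of origin of every offspring haplotype is determined separately
#' from KIR types (exact match) and SNP haplotypes (fewer than
#' `max_mismatch` mismatches), the two sources are merged, haplotypes with
#' irreconcilable evidence are excluded, related haplotypes are pruned with
#' [select_unrelated()], and the surviving haplotypes with complete SNP and
#' KIR data form the reference panel.
#'
#' @param pedigree Data frame with columns `family_id`, `person_id`,
#'   `father_id`, `mother_id` (`NA`/`""`/`"0"` for founders).
#' @param snp_panel A [haplotype_panel()] whose haplotype ids are
#'   `<person>_1` / `<person>_2` for every person with SNP data.
#' @param kir_table Per-haplotype KIR type data frame (rownames
#'   `<person>_1` / `<person>_2`) for every person with KIR data.
#' @param max_mismatch Strict SNP mismatch bound for haplotype matching.
#' @return List with `panel` (a [reference_panel()]), `kept` (haplotype
#'   ids), and `log` (data frame of per-haplotype decisions).
#' @export
build_reference_panel <- function(pedigree, snp_panel, kir_table,
                                  max_mismatch = 20L) {
  ped <- as.data.frame(pedigree, stringsAsFactors = FALSE)
  stopifnot(all(c("family_id", "person_id", "father_id", "mother_id")
                %in% names(ped)))
  norm_id <- function(x) ifelse(is.na(x) | x %in% c("", "0"), NA_character_, x)
  ped$father_id <- norm_id(as.character(ped$father_id))
  ped$mother_id <- norm_id(as.character(ped$mother_id))

  kir <- as.data.frame(kir_table, stringsAsFactors = FALSE)
  haps_of <- function(p) paste0(p, c("_1", "_2"))
  has_snp <- function(p) all(haps_of(p) %in% snp_panel$haplotype_ids)
  has_kir <- function(p) all(haps_of(p) %in% rownames(kir))
  has_any <- function(p) has_snp(p) || has_kir(p)

  snp_row <- function(h) snp_panel$alleles[match(h, snp_panel$haplotype_ids), ]
  kir_row <- function(h) {
    v <- unlist(kir[h, , drop = TRUE])
    setNames(as.character(v), names(kir))
  }
  hap_key <- function(h) {
    paste(if (has_kir_h(h)) paste(kir_row(h), collapse = ","),
          if (has_snp_h(h)) paste(snp_row(h), collapse = ""), sep = "|")
  }
  has_snp_h <- function(h) h %in% snp_panel$haplotype_ids
  has_kir_h <- function(h) h %in% rownames(kir)

  kept <- character(0)
  log_rows <- list()
  note <- function(h, fam, decision, detail = "") {
    log_rows[[length(log_rows) + 1L]] <<-
      data.frame(family_id = fam, haplotype_id = h, decision = decision,
                 detail = detail, stringsAsFactors = FALSE)
  }

  for (fam in unique(ped$family_id)) {
    members <- ped[ped$family_id == fam, , drop = FALSE]
    fathers <- unique(stats::na.omit(members$father_id))
    mothers <- unique(stats::na.omit(members$mother_id))
    if (length(fathers) > 1L || length(mothers) > 1L)
      stop("family ", fam, " has more than one father or mother")
    father <- if (length(fathers) && has_any(fathers)) fathers else NULL
    mother <- if (length(mothers) && has_any(mothers)) mothers else NULL
    children <- members$person_id[!is.na(members$father_id) |
                                  !is.na(members$mother_id)]
    children <- children[vapply(children, has_any, logical(1L))]

    par_mat <- function(p, getter, have) {
      if (is.null(p)) return(NULL)
      hs <- haps_of(p)[vapply(haps_of(p), have, logical(1L))]
      if (!length(hs)) return(NULL)
      m <- do.call(rbind, lapply(hs, getter))
      rownames(m) <- hs
      m
    }
    f_kir <- par_mat(father, kir_row, has_kir_h)
    m_kir <- par_mat(mother, kir_row, has_kir_h)
    f_snp <- par_mat(father, snp_row, has_snp_h)
    m_snp <- par_mat(mother, snp_row, has_snp_h)

    off <- NULL
    for (ch in children) for (h in haps_of(ch)) {
      if (!has_snp_h(h) && !has_kir_h(h)) next
      a_kir <- if (has_kir_h(h) && (!is.null(f_kir) || !is.null(m_kir)))
        match_by_kir(kir_row(h), f_kir, m_kir)$origin else "unassigned"
      a_snp <- if (has_snp_h(h) && (!is.null(f_snp) || !is.null(m_snp)))
        match_by_snp(snp_row(h), f_snp, m_snp, max_mismatch)$origin
        else "unassigned"
      mg <- merge_assignments(a_kir, a_snp)
      off <- rbind(off, data.frame(haplotype_id = h, origin = mg$origin,
                                   evidence = mg$evidence,
                                   stringsAsFactors = FALSE))
    }
    off_keys <- if (is.null(off)) character(0)
      else setNames(vapply(off$haplotype_id, hap_key, character(1L)),
                    off$haplotype_id)

    fh <- if (!is.null(father))
      haps_of(father)[vapply(haps_of(father), function(h)
        has_snp_h(h) || has_kir_h(h), logical(1L))] else NULL
    mhp <- if (!is.null(mother))
      haps_of(mother)[vapply(haps_of(mother), function(h)
        has_snp_h(h) || has_kir_h(h), logical(1L))] else NULL

    fam_keep <- select_unrelated(list(father_haps = fh, mother_haps = mhp,
                                      offspring = off, hap_key = off_keys))
    if (!is.null(off)) {
      for (i in seq_len(nrow(off))) {
        h <- off$haplotype_id[i]
        if (h %in% fam_keep) next
        why <- if (off$origin[i] == "ambiguous") "ambiguous_origin"
               else if (off$origin[i] != "unassigned") "copy_of_parent"
               else "duplicate_within_family"
        note(h, fam, "excluded", why)
      }
    }
    for (h in fam_keep) {
      if (has_snp_h(h) && has_kir_h(h)) {
        kept <- c(kept, h)
        note(h, fam, "kept", "")
      } else {
        note(h, fam, "excluded", "incomplete_data")
      }
    }
  }

  if (!length(kept)) stop("no haplotypes survive panel construction")
  panel <- reference_panel(snp_panel[kept, ],
                           kir[kept, , drop = FALSE])
  list(panel = panel, kept = kept, log = do.call(rbind, log_rows))
}

#' Randomly pair haplotypes into pseudo-individuals
#'
#' Pairs reference haplotypes at random without replacement to form
#' artificial diploids (for methods that require unphased individual-level
#' input).  With an odd number of haplotypes, the one left after the seeded
#' shuffle is discarded.
#'
#' @param hap_ids Character vector of haplotype ids (length >= 2).
#' @param seed Integer seed; the pairing is deterministic given the seed.
#' @return Two-column character matrix, one row per pseudo-individual.
#' @export
pair_pseudo_individuals <- function(hap_ids, seed = 1L) {
  n <- length(hap_ids)
  if (n < 2L) stop("need at least 2 haplotypes to pair")
  ord <- .seeded_sample(hap_ids, n, seed)
  n_even <- n - n %% 2L
  cbind(ord[seq(1L, n_even, by = 2L)], ord[seq(2L, n_even, by = 2L)])
}
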