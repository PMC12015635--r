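#' Squared Pearson correlation of genotype dosages
#'
#' Computed over samples typed at both sites (pairwise deletion). Because
#' dosage enters symmetrically, the value is invariant to swapping the
#' allele coding of either site (`dosage -> 2 - dosage`).
#'
#' @param x,y dosage vectors (0/1/2/`NA`) of equal length.
#' @return Squared correlation in `[0,1]`, or `NA` when fewer than two
#'   shared samples or either vector is constant after pairwise deletion.
#' @export
#' @examples
#' dosage_r2(c(0, 1, 2, 1, 0), c(0, 1, 1, 1, 0))
dosage_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("dosage_r2: vectors differ in length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Prune candidates to an approximately unlinked set
#'
#' Evaluates every same-contig pair of candidate sites within `window` bp.
#' For each pair with `r^2 > r2_max` one site is dropped, chosen by (1) more
#' missing data dropped, (2) tie: lower enzyme-accessibility rank dropped
#' (optional user-supplied ordering; ties otherwise neutral), (3) tie:
#' larger coordinate dropped. Pairs are resolved greedily in coordinate
#' order; the survivors contain no pair above the threshold.
#'
#' @param sites data.frame with `snp_id`, `contig`, `pos` for the candidates.
#' @param dosage dosage matrix with rownames matching `snp_id`.
#' @param r2_max linkage threshold (pairs strictly above it are resolved).
#' @param window maximum intra-contig distance (bp) at which pairs are
#'   evaluated.
#' @param enzyme_rank optional named numeric vector (higher = more
#'   accessible enzyme) used as the second tie-break.
#' @return `list(kept = <snp_ids>, dropped = <data.frame with snp_id,
#'   linked_to, r_squared, rule>, pairs = <all evaluated pairs>)`.
#' @export
prune_linked <- function(sites, dosage, r2_max = 0.2, window = 1e6,
                         enzyme_rank = NULL) {
  stopifnot(all(sites$snp_id %in% rownames(dosage)))
  ord <- order(sites$contig, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  n_missing <- rowSums(is.na(dosage[sites$snp_id, , drop = FALSE]))
  rank_of <- function(id) {
    if (is.null(enzyme_rank) || !id %in% names(enzyme_rank)) 0 else enzyme_rank[[id]]
  }
  alive <- stats::setNames(rep(TRUE, nrow(sites)), sites$snp_id)
  pairs <- NULL
  dropped <- NULL
  n <- nrow(sites)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (sites$contig[i] != sites$contig[j]) next
        dist <- abs(sites$pos[j] - sites$pos[i])
        if (dist > window) next
        a <- sites$snp_id[i]; b <- sites$snp_id[j]
        r2 <- dosage_r2(dosage[a, ], dosage[b, ])
        pairs <- rbind(pairs, data.frame(site_a = a, site_b = b,
                                         distance = dist, r_squared = r2,
                                         n_shared = sum(!is.na(dosage[a, ]) & !is.na(dosage[b, ])),
                                         stringsAsFactors = FALSE))
        if (is.na(r2) || r2 <= r2_max) next
        if (!alive[[a]] || !alive[[b]]) next
        rule <- "missingness"
        if (n_missing[a] > n_missing[b]) {
          loser <- a
        } else if (n_missing[b] > n_missing[a]) {
          loser <- b
        } else if (rank_of(a) != rank_of(b)) {
          rule <- "enzyme_rank"
          loser <- if (rank_of(a) < rank_of(b)) a else b
        } else {
          rule <- "coordinate"
          loser <- b # larger coordinate (j > i in coordinate order)
        }
        alive[[loser]] <- FALSE
        dropped <- rbind(dropped, data.frame(
          snp_id = loser, linked_to = if (loser == a) b else a,
          r_squared = r2, rule = rule, stringsAsFactors = FALSE))
      }
    }
  }
  list(kept = names(alive)[alive], dropped = dropped, pairs = pairs)
}
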