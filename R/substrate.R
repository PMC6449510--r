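# Substrate-type classification, degree-of-reduction lookup, and group
# comparisons (one-way ANOVA + Tukey HSD with a compact letter display).

#' Substrate category levels
#'
#' The thirteen categories of the classification scheme: four glucose
#' variants, the two organic-acid groups, high-molecular compounds with and
#' without inorganic N, plant residue with and without inorganic N, and the
#' three inorganic additions.
#'
#' @return Character vector of category names.
#' @export
substrate_categories <- function() {
  c("glucose", "glucose_plus_N", "glucose_plus_C", "glucose_plus_salt",
    "amino_acid", "other_acid", "high_molecular", "high_molecular_plus_N",
    "plant_residue", "residue_plus_N", "water", "inorganic_N", "mixture")
}

# default keyword lexicon: category -> regex alternatives (case-insensitive,
# matched against the whole free-text descriptor)
.base_keywords <- list(
  amino_acid = c("amino acid", "glycine", "alanine", "glutamate", "glutamine",
                 "glutamic", "aspartate", "aspartic", "leucine", "isoleucine",
                 "lysine", "serine", "valine"),
  other_acid = c("oxal", "formate", "formic", "citrate", "citric", "malate",
                 "malic", "malonate", "succin", "pyruv", "lactate", "lactic",
                 "acetate", "acetic", "propionate", "butyrate", "oleate",
                 "oleic", "oxalic", "organic acid"),
  high_molecular = c("protein", "cellulose", "cellobiose", "cell wall",
                     "cell walls", "starch", "tripalmit", "palmitoyl",
                     "polyhydroxybutyrate", "chitin", "lignin",
                     "high[- ]molecular"),
  plant_residue = c("residue", "straw", "litter", "\\broots?\\b",
                    "\\bleaves\\b", "\\bleaf\\b", "\\bstems?\\b", "needle",
                    "\\bplant\\b", "\\bhay\\b"),
  glucose = c("glucose", "sucrose", "\\bsugar\\b", "fructose"),
  water = c("\\bwater\\b", "\\bh2o\\b"),
  mixture = c("mixture", "\\bmixed\\b", "inorganic solution"))

.n_modifier <- c("\\+\\s*n\\b", "ammonium", "nitrate", "\\bnh4", "\\bno3",
                 "\\burea\\b", "inorganic n")
.salt_modifier <- c("\\bsalt\\b", "\\bkcl\\b", "k2so4", "\\bnacl\\b",
                    "phosphate", "\\bk2hpo4\\b", "\\bkh2po4\\b")

.matches_any <- function(text, patterns)
  any(vapply(patterns, function(p) grepl(p, text, ignore.case = TRUE,
                                         perl = TRUE), logical(1)))

#' Classify a free-text substrate description
#'
#' Deterministic, case-insensitive keyword rules mapping the free-text
#' substrate descriptor of a literature record to one of the categories in
#' [substrate_categories()]. A nitrogen modifier (`"+ N"`, ammonium,
#' nitrate, urea, ...) combined with a glucose, high-molecular, or
#' plant-residue base maps to the corresponding `_plus_N` variant; an
#' inorganic-salt modifier with glucose maps to `glucose_plus_salt`; glucose
#' combined with a second organic-carbon substrate maps to
#' `glucose_plus_C`. Text matching no rule is an error — the classifier
#' never guesses.
#'
#' @param substrate_text Character vector of descriptors (non-empty).
#' @param synonyms Optional user lexicon extending the built-in rules: a
#'   data.frame with columns `keyword` (regex) and `category`, e.g. read
#'   from a site-specific CSV.
#' @return Character vector of categories, same length as `substrate_text`.
#' @export
#' @examples
#' classify_substrate(c("glucose + NH4NO3", "cellobiose", "maize leaves"))
classify_substrate <- function(substrate_text, synonyms = NULL) {
  if (length(substrate_text) == 0) stop("substrate_text must be non-empty")
  extra <- list()
  if (!is.null(synonyms)) {
    stopifnot(all(c("keyword", "category") %in% names(synonyms)))
    extra <- split(as.character(synonyms$keyword), as.character(synonyms$category))
  }
  vapply(substrate_text, function(text) {
    if (is.na(text) || !nzchar(trimws(text)))
      stop("empty substrate text cannot be classified")
    # user synonyms take precedence and may name any category directly
    for (cat in names(extra))
      if (.matches_any(text, extra[[cat]])) return(cat)
    has_N <- .matches_any(text, .n_modifier)
    has_salt <- .matches_any(text, .salt_modifier)
    is_glucose <- .matches_any(text, .base_keywords$glucose)
    other_C <- .matches_any(text, c(.base_keywords$amino_acid,
                                    .base_keywords$other_acid,
                                    .base_keywords$high_molecular,
                                    .base_keywords$plant_residue)) ||
      grepl("\\+\\s*c\\b", text, ignore.case = TRUE)
    if (is_glucose) {
      if (other_C) return("glucose_plus_C")
      if (has_N) return("glucose_plus_N")
      if (has_salt) return("glucose_plus_salt")
      return("glucose")
    }
    if (.matches_any(text, .base_keywords$amino_acid)) return("amino_acid")
    if (.matches_any(text, .base_keywords$other_acid)) return("other_acid")
    if (.matches_any(text, .base_keywords$high_molecular))
      return(if (has_N) "high_molecular_plus_N" else "high_molecular")
    if (.matches_any(text, .base_keywords$plant_residue))
      return(if (has_N) "residue_plus_N" else "plant_residue")
    if (.matches_any(text, .base_keywords$mixture)) return("mixture")
    if (.matches_any(text, .base_keywords$water)) return("water")
    if (has_N) return("inorganic_N")
    stop("unclassifiable substrate text: '", text, "'")
  }, character(1), USE.NAMES = FALSE)
}

#' The packaged degree-of-reduction table
#'
#' Twenty-six single substances with their degree of reduction (gamma_S,
#' available electrons per mole of carbon) and classification group. Values
#' follow the standard compilation for microbial growth stoichiometry; the
#' table spans gamma_S 1 (oxalate) to 6, with glucose at 4 and the amino
#' acids concentrated at 3.6 and 5. Entries whose identity is not pinned
#' down by the source compilation are marked `paper_ambiguous`. The file is
#' shipped as editable CSV at
#' `system.file("extdata", "gamma_s_table.csv", package = "soilcue")`.
#'
#' @return data.frame with columns `substance`, `gamma_s`, `group`,
#'   `paper_ambiguous`.
#' @export
gamma_s_table <- function() {
  utils::read.csv(system.file("extdata", "gamma_s_table.csv",
                              package = "soilcue", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Degree-of-reduction lookup
#'
#' Case-insensitive lookup of a single substance in the packaged table.
#' Mixed substrates, plant residue, water, and inorganic N have no defined
#' gamma_S; for those (and any other unknown name) the lookup returns
#' `NULL` — not-found is a value, not an error.
#'
#' @param substance Substance name (e.g. `"glucose"`).
#' @return One-row data.frame (`substance`, `gamma_s`, `group`,
#'   `paper_ambiguous`), or `NULL` if not found.
#' @export
#' @examples
#' gamma_s("glucose")$gamma_s  # 4
gamma_s <- function(substance) {
  tab <- gamma_s_table()
  hit <- tab[tolower(tab$substance) == tolower(trimws(substance)), , drop = FALSE]
  if (nrow(hit) == 0) return(NULL)
  rownames(hit) <- NULL
  hit
}

#' Energy limitation from the degree of reduction
#'
#' Substrates whose degree of reduction falls below that of microbial
#' biomass (about 4.2) limit growth energetically; at or above it, CUE can
#' reach its metabolic maximum.
#'
#' @param gamma Degree of reduction, in \[1, 8\].
#' @return `"energy_limited"` if `gamma < 4.2`, else `"at_maximum"`
#'   (vectorized).
#' @export
energy_limitation <- function(gamma) {
  if (any(!is.finite(gamma) | gamma < 1 | gamma > 8))
    stop("degree of reduction must lie in [1, 8]")
  ifelse(gamma < 4.2, "energy_limited", "at_maximum")
}

# Compact letter display: one letter per maximal clique of the
# "not significantly different" graph. This is exact by construction --
# every non-significant pair lies in some maximal clique (shares a letter)
# and a clique can never contain a significant pair. Letters are ordered by
# each clique's highest group mean, matching the usual top-down display.
.compact_letters <- function(groups, means, p_matrix, alpha = 0.05) {
  k <- length(groups)
  adj <- p_matrix[groups, groups, drop = FALSE] >= alpha
  diag(adj) <- FALSE    # no self-loops: a vertex is not its own neighbour
  cliques <- list()
  bron_kerbosch <- function(R, P, X) {
    if (length(P) == 0 && length(X) == 0) {
      cliques[[length(cliques) + 1]] <<- R
      return(invisible())
    }
    for (v in P) {
      nb <- which(adj[v, ])
      bron_kerbosch(c(R, v), intersect(P, nb), intersect(X, nb))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  bron_kerbosch(integer(0), seq_len(k), integer(0))
  best_mean <- vapply(cliques, function(cl) max(means[cl]), numeric(1))
  cliques <- cliques[order(-best_mean)]
  letters_out <- stats::setNames(rep("", k), groups)
  for (s in seq_along(cliques))
    letters_out[cliques[[s]]] <- paste0(letters_out[cliques[[s]]], letters[s])
  letters_out
}

#' Compare CUE across groups: ANOVA, Tukey HSD, compact letters
#'
#' One-way analysis of variance of CUE across the levels of a grouping
#' column, followed by Tukey honestly-significant-difference pairwise
#' comparisons and a compact letter display at `alpha = 0.05` (groups
#' sharing no letter differ significantly).
#'
#' @param ds Observation data.frame.
#' @param grouping Grouping column name (e.g. `"substrate_category"` or a
#'   gamma_S group column).
#' @param alpha Significance level for the letter display; default 0.05.
#' @return List of class `cue_group_comparison`: `summary` (per-group n,
#'   mean, sd, letter), `anova_F`, `anova_p`, `tukey` (pairwise table from
#'   [stats::TukeyHSD()]), `p_matrix` (symmetric pairwise adjusted
#'   p-values), `alpha`.
#' @export
compare_cue_groups <- function(ds, grouping, alpha = 0.05) {
  if (!grouping %in% names(ds)) stop("unknown grouping field: ", grouping)
  keep <- !is.na(ds$cue) & !is.na(ds[[grouping]])
  cue <- ds$cue[keep]
  grp <- factor(ds[[grouping]][keep])
  counts <- table(grp)
  if (length(counts) < 2 || any(counts < 2))
    stop("need >= 2 groups with >= 2 records each; got ",
         paste(names(counts), counts, sep = "=", collapse = ", "))
  fit <- stats::aov(cue ~ grp)
  an <- summary(fit)[[1]]
  tuk <- stats::TukeyHSD(fit)$grp
  lev <- levels(grp)
  p_matrix <- matrix(1, length(lev), length(lev), dimnames = list(lev, lev))
  for (r in rownames(tuk)) {
    pair <- strsplit(r, "-", fixed = TRUE)[[1]]
    p_matrix[pair[1], pair[2]] <- p_matrix[pair[2], pair[1]] <- tuk[r, "p adj"]
  }
  means <- tapply(cue, grp, mean)
  letters_disp <- .compact_letters(lev, means[lev], p_matrix, alpha)
  summary_df <- data.frame(group = lev, n = as.integer(counts[lev]),
                           mean = as.numeric(means[lev]),
                           sd = as.numeric(tapply(cue, grp, stats::sd)[lev]),
                           letter = letters_disp, stringsAsFactors = FALSE)
  rownames(summary_df) <- NULL
  structure(list(summary = summary_df,
                 anova_F = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1],
                 tukey = tuk, p_matrix = p_matrix, alpha = alpha),
            class = "cue_group_comparison")
}

#' @export
print.cue_group_comparison <- function(x, ...) {
  cat("One-way ANOVA: F =", signif(x$anova_F, 4),
      ", p =", format.pval(x$anova_p, digits = 3), "\n")
  print(transform(x$summary, mean = round(mean, 3), sd = round(sd, 3)))
  invisible(x)
}

#' Effect of nitrogen addition on mean CUE
#'
#' Percent change of mean CUE between a base substrate category and its
#' `_plus_N` variant: `100 * (mean(base + N) - mean(base)) / mean(base)`.
#' Negative values are declines.
#'
#' @param ds Observation data.frame with `cue` and `substrate_category`.
#' @param base Base category: one of `"glucose"`, `"high_molecular"`,
#'   `"plant_residue"`.
#' @return Scalar percent change.
#' @export
nitrogen_effect <- function(ds, base = c("high_molecular", "plant_residue",
                                         "glucose")) {
  base <- match.arg(base)
  plus_n <- switch(base, glucose = "glucose_plus_N",
                   high_molecular = "high_molecular_plus_N",
                   plant_residue = "residue_plus_N")
  keep <- !is.na(ds$cue) & !is.na(ds$substrate_category)
  v_base <- ds$cue[keep & ds$substrate_category == base]
  v_plus <- ds$cue[keep & ds$substrate_category == plus_n]
  if (length(v_base) == 0) stop("no records in base category '", base, "'")
  if (length(v_plus) == 0) stop("no records in category '", plus_n, "'")
  100 * (mean(v_plus) - mean(v_base)) / mean(v_base)
}
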