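#' Deterministic worked-example fixture
#'
#' Builds, with no randomness, a per-protein contrast-call set over 3987
#' proteins plus a 33-class category annotation that jointly satisfy the
#' headline counts of the motivating three-cohort study: 450 proteins
#' altered by disease (207 up, 243 down; 11.3% of the proteome), 283
#' altered under therapy (153 up, 130 down; 7.1%); reversal classes 64
#' FULL (32 up / 32 down), 228 PARTIAL (222 type A, 6 type B; 91 up / 137
#' down) and 158 NONE; 12 up- and 14 down-overrepresented functional
#' classes of which 9 and 13 are remediated (22/26 = 85%). The treated
#' contrast closes arithmetically: the 153 up calls are the 84 still-up
#' non-reversed proteins, 3 type-B residuals and 66 newly-up proteins
#' (84 + 3 + 66 = 153), and likewise 74 + 3 + 53 = 130 down.
#'
#' Protein identities and class labels are synthetic (`P0001...`,
#' `C01...C33`); per-class identities are allocated deterministically
#' subject to the aggregate counts. The type-B split (3 up / 3 down) and
#' the still-significant/new-protein closure are one consistent solution,
#' chosen as a convention. Fold changes and p-values are stylized values
#' consistent with every significance flag at the default two-fold,
#' p < 0.01 gates.
#'
#' @return A list: `contrasts` (named list of three contrast tables,
#'   `mi_vs_ctrl`, `micp_vs_mi`, `micp_vs_ctrl`), `categories` (named
#'   vector protein -> class), `class_counts` (per-class disease/treated
#'   changed counts by direction), `n_proteins`.
#' @export
make_paper_fixture <- function() {
  n_proteins <- 3987L

  # per-role counts; roles are blocks of consecutive protein identifiers
  roles <- c(full_up = 32L, pa_up = 88L, pb_up = 3L, none_up = 84L,
             full_dn = 32L, pa_dn = 134L, pb_dn = 3L, none_dn = 74L,
             new_up = 66L, new_dn = 53L)
  roles <- c(roles, unaffected = n_proteins - sum(roles))
  role_of <- rep(names(roles), times = roles)
  ids <- sprintf("P%04d", seq_len(n_proteins))

  # stylized (log2fc, p) per role for the three contrasts; flags follow
  # from the default gates
  vals <- list(
    #          mi_vs_ctrl      micp_vs_mi     micp_vs_ctrl
    full_up  = c(+2.0, 1e-4,   -2.0, 1e-4,    +0.2, 0.6),
    pa_up    = c(+2.0, 1e-4,   -1.2, 0.05,    +0.8, 0.2),
    pb_up    = c(+3.0, 1e-5,   -1.5, 1e-3,    +1.5, 1e-3),
    none_up  = c(+2.0, 1e-4,    0.0, 0.9,     +2.0, 1e-4),
    full_dn  = c(-2.0, 1e-4,   +2.0, 1e-4,    -0.2, 0.6),
    pa_dn    = c(-2.0, 1e-4,   +1.2, 0.05,    -0.8, 0.2),
    pb_dn    = c(-3.0, 1e-5,   +1.5, 1e-3,    -1.5, 1e-3),
    none_dn  = c(-2.0, 1e-4,    0.0, 0.9,     -2.0, 1e-4),
    new_up   = c(+0.2, 0.5,    +1.3, 5e-3,    +1.5, 1e-3),
    new_dn   = c(-0.2, 0.5,    -1.3, 5e-3,    -1.5, 1e-3),
    unaffected = c(0.0, 1.0,    0.0, 1.0,      0.0, 1.0)
  )
  vmat <- do.call(rbind, vals)[role_of, ]
  mk_tab <- function(j, label) {
    tab <- data.frame(protein_id = ids,
                      log2fc = vmat[, 2 * j - 1],
                      p_value = vmat[, 2 * j],
                      significant = FALSE, direction = "none",
                      n_a = 4L, n_b = 4L, stringsAsFactors = FALSE)
    tab <- call_significance(tab, de_thresholds())
    attr(tab, "contrast") <- label
    class(tab) <- c("contrast_table", "data.frame")
    tab
  }
  contrasts <- list(mi_vs_ctrl = mk_tab(1, "MI_vs_Ctrl"),
                    micp_vs_mi = mk_tab(2, "MI+CP_vs_MI"),
                    micp_vs_ctrl = mk_tab(3, "MI+CP_vs_Ctrl"))

  # 33-class partition: 12 classes overrepresented for upregulation (9 of
  # them remediated), 14 for downregulation (13 remediated), 7 background
  # classes absorbing the rest; per-class role allocation closes every
  # aggregate count
  sizes <- c(rep(40L, 26), rep(420L, 6), 427L)
  alloc <- rbind(
    matrix(rep(c(2, 2, 0, 2, 0,  0, 1, 0, 1, 0), 9), 9, byrow = TRUE),
    matrix(rep(c(1, 1, 0, 4, 2,  0, 1, 0, 1, 0), 3), 3, byrow = TRUE),
    matrix(rep(c(0, 1, 0, 1, 0,  2, 3, 0, 2, 0), 13), 13, byrow = TRUE),
    c(0, 1, 0, 1, 0,  0, 2, 0, 5, 2),
    c(2, 8, 1, 5, 10,  1, 12, 1, 4, 8),
    c(2, 8, 1, 5, 10,  1, 12, 1, 4, 8),
    c(2, 8, 1, 4, 10,  1, 11, 1, 4, 8),
    c(2, 8, 0, 5, 10,  1, 12, 0, 4, 8),
    c(1, 7, 0, 7, 10,  1, 12, 0, 4, 7),
    c(1, 7, 0, 7, 10,  1, 11, 0, 5, 6),
    c(1, 7, 0, 7, 0,   0, 11, 0, 6, 6)
  )
  colnames(alloc) <- c("full_up", "pa_up", "pb_up", "none_up", "new_up",
                       "full_dn", "pa_dn", "pb_dn", "none_dn", "new_dn")
  class_labels <- sprintf("C%02d", seq_len(33))

  categories <- stats::setNames(rep(NA_character_, n_proteins), ids)
  for (r in colnames(alloc)) {
    # allocate this role's proteins to classes in class order
    cls_seq <- rep(class_labels, times = alloc[, r])
    categories[role_of == r] <- cls_seq
  }
  # fill remaining class capacity with unaffected proteins
  used <- table(factor(categories, levels = class_labels))
  fill_seq <- rep(class_labels, times = sizes - as.integer(used))
  categories[role_of == "unaffected"] <- fill_seq

  mi_dir <- contrasts$mi_vs_ctrl$direction
  trt_dir <- contrasts$micp_vs_ctrl$direction
  cls_f <- factor(categories, levels = class_labels)
  class_counts <- data.frame(
    category = class_labels, size = sizes,
    disease_up = as.integer(table(cls_f[mi_dir == "up"])),
    disease_down = as.integer(table(cls_f[mi_dir == "down"])),
    treated_up = as.integer(table(cls_f[trt_dir == "up"])),
    treated_down = as.integer(table(cls_f[trt_dir == "down"])),
    stringsAsFactors = FALSE)

  list(contrasts = contrasts, categories = categories,
       class_counts = class_counts, n_proteins = n_proteins)
}
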