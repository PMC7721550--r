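# Packaged fixture federations for the two worked examples: a clinical
# cohort service ("icees") asserting differentially diagnosed diseases, and
# a curated biomedical linkage service ("robokop") asserting disease-gene
# and gene-chemical associations. Identifiers are synthetic (FIX: prefix);
# labels carry the published entity names, so set-equality checks compare
# labels. Both shards contain distractor content that the canonical queries
# must not return.

UC1_CHEMICALS <- c(
  "calcitriol", "calcium atom", "vitamin D", "calcium carbonate", "phosphane",
  "adenine", "phosphate", "phosphorous", "maxacalcitol", "calciol", "calcium",
  "lithium hydride", "cinacalcet"
)

UC2_CHEMICALS <- c(
  "polybrominated biphenyls", "pentabromodiphenyl ether",
  "halogenated diphenyl ethers", "2,2',4,5'-tetrabromodiphenyl ether",
  "3,5-diiodo-L-tyrosine", "triclosan", "trihydroiodine", "erythrosine",
  "rose bengal", "hydrogen iodide", "benzbromarone", "chlorobiphenyl",
  "fenson", "NADPH", "NADP(+)", "flavin mononucleotide", "eosin B"
)

node_row <- function(id, concept, label = id, attributes = NULL) {
  tibble::tibble(id = id, concept = concept, label = label,
                 attributes = list(attributes %||%
                                     stats::setNames(list(), character())))
}

edge_row <- function(subject, object, predicate, source,
                     weight = NA_real_) {
  tibble::tibble(subject = subject, object = object, predicate = predicate,
                 weight = weight, source = source)
}

# Union of shard graphs: node sources unioned on shared ids, edges
# deduplicated on (subject, predicate, object, source).
union_kgs <- function(kgs) {
  nodes <- purrr::map_dfr(kgs, function(kg) kg$nodes)
  dup_ids <- unique(nodes$id[duplicated(nodes$id)])
  if (length(dup_ids)) {
    is_dup <- nodes$id %in% dup_ids
    singles <- nodes[!is_dup, ]
    groups <- split(which(is_dup), nodes$id[is_dup])
    first <- unname(vapply(groups, `[[`, integer(1), 1L))
    reconciled <- tibble::tibble(
      id = nodes$id[first],
      concept = nodes$concept[first],
      label = nodes$label[first],
      attributes = unname(lapply(groups, function(idx)
        purrr::reduce(nodes$attributes[idx], utils::modifyList))),
      sources = unname(lapply(groups, function(idx)
        sort(unique(unlist(nodes$sources[idx]))))))
    nodes <- dplyr::bind_rows(singles, reconciled)
  }
  edges <- purrr::map_dfr(kgs, function(kg) kg$edges)
  if (nrow(edges)) edges <- edges[!duplicated(edge_key(edges)), ]
  knowledge_graph(nodes, edges)
}

#' Build a packaged fixture federation
#'
#' Case 1: a cohort service asserting diseases differentially diagnosed by
#' sex — among them ovarian cancer — federated with a curated service
#' linking ovarian cancer to the gene PTH (parathyroid hormone) and PTH to
#' 13 chemical substances (calcitriol through cinacalcet). Case 2: diseases
#' differential by rural/urban residence — among them croup — with the gene
#' IYD (iodotyrosine deiodinase) and its 17 associated chemicals. Both
#' cases include distractor paths (diseases with no downstream gene,
#' gene-phenotype and disease-chemical edges off the canonical path).
#'
#' @param case_id 1 or 2.
#' @param model A [concept_model()].
#' @return A `fixture_federation`: `registry`, `union_kg`, `truth` (expected
#'   labels), `query_text` (the canonical query), `model`.
#' @export
build_use_case <- function(case_id, model = default_concept_model()) {
  if (!length(case_id) == 1 || !case_id %in% c(1, 2)) {
    abort_argument("case_id must be 1 or 2")
  }
  if (case_id == 1) {
    cohort <- "FIX:cohort_sex"
    cohort_label <- "UNC Health patient cohort stratified by sex"
    disease_id <- "FIX:ovarian_cancer"; disease_label <- "ovarian cancer"
    gene_id <- "FIX:PTH"; gene_label <- "PTH"
    chems <- UC1_CHEMICALS
    chem_ids <- sprintf("FIX:uc1_chem_%02d", seq_along(chems))
    extra_diseases <- tibble::tibble(
      id = c("FIX:prostate_cancer", "FIX:breast_cancer"),
      label = c("prostate cancer", "breast cancer"))
    distractor_disease <- "FIX:lung_cancer"; distractor_label <- "lung cancer"
    distractor_gene <- "FIX:BRCA1"
    distractor_chem <- "FIX:tamoxifen"
    phenotype_id <- "FIX:hypercalcemia"; phenotype_label <- "hypercalcemia"
    direct_chem <- "FIX:cisplatin"
    icees_attr <- list(feature = "Sex", p_value = 0.03)
  } else {
    cohort <- "FIX:cohort_residence"
    cohort_label <- "UNC Health patient cohort stratified by residence"
    disease_id <- "FIX:croup"; disease_label <- "croup"
    gene_id <- "FIX:IYD"; gene_label <- "IYD"
    chems <- UC2_CHEMICALS
    chem_ids <- sprintf("FIX:uc2_chem_%02d", seq_along(chems))
    extra_diseases <- tibble::tibble(
      id = c("FIX:asthma", "FIX:copd"),
      label = c("asthma", "chronic obstructive pulmonary disease"))
    distractor_disease <- "FIX:influenza"; distractor_label <- "influenza"
    distractor_gene <- "FIX:TPO"
    distractor_chem <- "FIX:oseltamivir"
    phenotype_id <- "FIX:stridor"; phenotype_label <- "stridor"
    direct_chem <- "FIX:dexamethasone"
    icees_attr <- list(feature = "Residence", p_value = 0.04)
  }

  icees_nodes <- dplyr::bind_rows(
    node_row(cohort, "population_of_individual_organisms", cohort_label),
    node_row(disease_id, "disease", disease_label, icees_attr),
    node_row(extra_diseases$id[1], "disease", extra_diseases$label[1]),
    node_row(extra_diseases$id[2], "disease", extra_diseases$label[2]),
    node_row("FIX:pm2_5", "environmental_feature", "airborne particulates PM2.5")
  )
  icees_edges <- dplyr::bind_rows(
    edge_row(cohort, disease_id, "associated_with", "icees"),
    edge_row(cohort, extra_diseases$id[1], "associated_with", "icees"),
    edge_row(cohort, extra_diseases$id[2], "associated_with", "icees"),
    edge_row(cohort, "FIX:pm2_5", "associated_with", "icees")
  )
  icees_kg <- knowledge_graph(icees_nodes, icees_edges)

  robokop_nodes <- dplyr::bind_rows(
    node_row(disease_id, "disease", disease_label,
             list(mondo_exact = paste0("MONDO:", disease_label))),
    node_row(gene_id, "gene", gene_label, list(hgnc_symbol = gene_label)),
    purrr::map2_dfr(chem_ids, chems, function(id, lb)
      node_row(id, "chemical_substance", lb)),
    node_row(distractor_disease, "disease", distractor_label),
    node_row(distractor_gene, "gene", sub("^FIX:", "", distractor_gene)),
    node_row(distractor_chem, "chemical_substance",
             sub("^FIX:", "", distractor_chem)),
    node_row(phenotype_id, "phenotypic_feature", phenotype_label),
    node_row(direct_chem, "chemical_substance", sub("^FIX:", "", direct_chem))
  )
  robokop_edges <- dplyr::bind_rows(
    edge_row(gene_id, disease_id, "gene_associated_with_condition",
             "robokop", weight = 0.8),
    purrr::map_dfr(chem_ids, function(id)
      edge_row(gene_id, id, "interacts_with", "robokop")),
    # distractor path: a disease the cohort service never returns
    edge_row(distractor_gene, distractor_disease,
             "gene_associated_with_condition", "robokop", weight = 0.9),
    edge_row(distractor_gene, distractor_chem, "interacts_with", "robokop"),
    # off-path edges: gene-phenotype, and a direct disease-chemical link
    edge_row(gene_id, phenotype_id, "has_phenotype", "robokop"),
    edge_row(disease_id, direct_chem, "interacts_with", "robokop",
             weight = 0.4)
  )
  robokop_kg <- knowledge_graph(robokop_nodes, robokop_edges)

  registry <- source_registry(list(
    fixture_source("icees", icees_kg, model),
    fixture_source("robokop", robokop_kg, model)
  ))
  query_path <- system.file("extdata", "queries",
                            paste0("use-case-", case_id, ".tql"),
                            package = "kgql")
  structure(
    list(
      registry = registry,
      union_kg = union_kgs(purrr::map(registry$sources, "kg")),
      truth = list(disease = disease_label, gene = gene_label,
                   chemicals = chems),
      query_text = paste(readLines(query_path, warn = FALSE), collapse = "\n"),
      model = model,
      seed = NA_integer_
    ),
    class = "fixture_federation"
  )
}

#' @export
print.fixture_federation <- function(x, ...) {
  cat("<fixture_federation> sources: ",
      paste(names(x$registry$sources), collapse = ", "), "; union: ",
      nrow(x$union_kg$nodes), " nodes, ", nrow(x$union_kg$edges), " edges\n",
      sep = "")
  invisible(x)
}
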