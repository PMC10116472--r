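# Reconstruction of the multi-class COVID-19 Outbreak schema: 22 classes
# extended from Schema.org, six of them principal resource types, built as
# per-class documents and merged into one schema (mirroring how the original
# was assembled). Support-class usage is encoded as lowerCamelCase linking
# properties whose range is the support class. Class descriptions record the
# free-text provenance of each class.

OUTBREAK_IRI <- "https://discovery.biothings.io/view/outbreak/"

# class name -> source Schema.org class. The source printed for
# ComputationalTool is "Software"; Schema.org has no such class, so
# SoftwareApplication is used.
outbreak_class_map <- function() {
  c(Analysis = "schema:CreativeWork",
    ClinicalTrial = "schema:MedicalStudy",
    ComputationalTool = "schema:SoftwareApplication",
    DataDownload = "schema:DataDownload",
    Dataset = "schema:Dataset",
    Protocol = "schema:HowTo",
    Publication = "schema:MedicalScholarlyArticle",
    ArmGroup = "schema:Thing",
    CitationObject = "schema:CreativeWork",
    Correction = "schema:CreativeWork",
    Eligibility = "schema:Thing",
    Instrument = "schema:Product",
    Intervention = "schema:Thing",
    MonetaryGrant = "schema:MonetaryGrant",
    Organization = "schema:Organization",
    Outcome = "schema:Thing",
    Person = "schema:Person",
    Product = "schema:Product",
    StudyEvent = "schema:Thing",
    StudyStatus = "schema:Thing",
    StudyDesign = "schema:Thing",
    StudyLocation = "schema:Place")
}

OUTBREAK_PRINCIPAL <- c("Analysis", "Dataset", "ClinicalTrial",
                        "ComputationalTool", "Protocol", "Publication")

# support class -> the classes its linking property attaches to
# ("All" = the six principal classes)
outbreak_used_in <- function() {
  all6 <- paste0("outbreak:", OUTBREAK_PRINCIPAL)
  ct <- "outbreak:ClinicalTrial"
  list(
    DataDownload = c("outbreak:ComputationalTool", "outbreak:Dataset"),
    ArmGroup = ct, CitationObject = all6, Correction = "outbreak:Publication",
    Eligibility = ct, Instrument = "outbreak:Protocol", Intervention = ct,
    MonetaryGrant = all6, Organization = all6, Outcome = ct,
    Person = all6, Product = "outbreak:Protocol",
    StudyEvent = ct, StudyStatus = ct, StudyDesign = ct, StudyLocation = ct)
}

outbreak_inspired_by <- function() {
  prs <- "NCT Clinical Trials PRS, WHO ClinicalTrials"
  c(Analysis = "Outbreak Protocol, Dataset Class, various COVID-19 Analyses",
    ClinicalTrial = prs,
    ComputationalTool = "Bioschemas, NIAID schema, Bio.tools schema",
    DataDownload = "NIAID schema",
    Dataset = "NIAID schema",
    Protocol = "Bioschemas LabProtocol, protocols.io",
    Publication = "NLM Medline, biorxiv, various journals",
    ArmGroup = prs, CitationObject = "Outbreak primary classes",
    Correction = "CitationObject", Eligibility = prs,
    Instrument = "Bioschemas LabProtocol, protocols.io", Intervention = prs,
    MonetaryGrant = "NIAID schema", Organization = "NIAID schema",
    Outcome = prs, Person = "NIAID schema",
    Product = "Bioschemas LabProtocol, protocols.io",
    StudyEvent = prs, StudyStatus = prs, StudyDesign = prs, StudyLocation = prs)
}

lower_camel <- function(x) paste0(tolower(substr(x, 1, 1)), substr(x, 2, nchar(x)))

#' Reconstruct the COVID-19 Outbreak schema
#'
#' Builds the 22-class Outbreak schema: six principal classes (`Analysis`,
#' `Dataset`, `ClinicalTrial`, `ComputationalTool`, `Protocol`,
#' `Publication`) plus support classes, each extended from its source
#' Schema.org class so that every class is rooted at `schema:Thing`.
#' Support-class usage is encoded through linking properties (e.g.
#' `outbreak:armGroup` on `ClinicalTrial` ranging over
#' `outbreak:ArmGroup`). `outbreak:Dataset` carries an `infectiousAgent`
#' property constrained to NCBI Taxonomy identifiers. Per-class documents
#' are assembled and merged into the single multi-class schema.
#'
#' @return A [schema_document()] with namespace `"outbreak"`.
#' @examples
#' ob <- build_outbreak_schema()
#' length(ob$classes)  # 22
#' @export
build_outbreak_schema <- function() {
  ctx <- context_map(outbreak = OUTBREAK_IRI, schema = SCHEMA_ORG_IRI)
  cmap <- outbreak_class_map()
  used_in <- outbreak_used_in()
  inspired <- outbreak_inspired_by()

  docs <- lapply(names(cmap), function(name) {
    id <- paste0("outbreak:", name)
    properties <- list()

    if (name %in% names(used_in)) {
      properties[[length(properties) + 1L]] <- property_definition(
        paste0("outbreak:", lower_camel(name)),
        domain_includes = used_in[[name]],
        range_includes = id,
        description = paste0("Links a resource to its ", name, " support record."))
    }

    validation <- NULL
    if (name == "Dataset") {
      properties[[length(properties) + 1L]] <- property_definition(
        "outbreak:infectiousAgent",
        domain_includes = id,
        range_includes = "schema:Thing",
        description = paste0("The pathogen the dataset concerns, standardized ",
                             "against the NCBI Taxonomy."))
      rs <- validation_ruleset(
        properties = list(
          name = list(type = "string"),
          description = list(type = "string"),
          url = list(type = "string", format = "uri"),
          identifier = list(type = "string"),
          keywords = list(type = "string"),
          infectiousAgent = list(type = "object")),
        required = c("name", "infectiousAgent"),
        recommended = c("description", "url"))
      rs <- attach_ontology_constraint(rs, "infectiousAgent",
        list(prefix = "NCBITaxon", iri = "http://purl.obolibrary.org/obo/NCBITaxon_"))
      rs <- set_cardinality(rs, "keywords", "many")
      validation <- rs
    } else if (name %in% OUTBREAK_PRINCIPAL) {
      validation <- validation_ruleset(
        properties = list(name = list(type = "string"),
                          description = list(type = "string")),
        required = "name",
        recommended = "description")
    }

    cls <- class_definition(
      id, sub_class_of = cmap[[name]],
      description = paste0(name, " class of the Outbreak schema, extended from ",
                           cmap[[name]], ". Inspired by: ", inspired[[name]], "."),
      validation = validation,
      principal = name %in% OUTBREAK_PRINCIPAL)
    schema_document("outbreak", ctx, list(cls), properties)
  })

  merge_schemas(docs, "outbreak")
}
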