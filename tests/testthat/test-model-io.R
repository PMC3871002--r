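test_that("SBML write/read round trip is lossless and deterministic", {
  models <- c(list(skeleton = make_skeleton_model()), micro_fixtures())
  for (nm in names(models)) {
    m <- models[[nm]]
    tf <- withr::local_tempfile(fileext = ".xml")
    write_sbml_model(m, tf)
    doc <- read_sbml_model(tf)
    expect_s3_class(doc, "model_document")
    expect_identical(doc$sbml_level_version, "L3V1")
    expect_equal(doc$model$metabolites, m$metabolites,
                 ignore_attr = "row.names")
    expect_true(isTRUE(reactions_equal(m, doc$model)), label = nm)
  }
  # byte-identical on repeated writes
  t1 <- withr::local_tempfile(); t2 <- withr::local_tempfile()
  write_sbml_model(models$skeleton, t1)
  write_sbml_model(models$skeleton, t2)
  expect_identical(readBin(t1, "raw", 1e6), readBin(t2, "raw", 1e6))
})

test_that("SBML reader survives non-ASCII names and rejects bad streams", {
  m <- cell_model(
    metabolite("asyn", name = "αSYN <aggregation-prone> & sticky"),
    list(reaction("in", c(asyn = 1), 0, 10, "input",
                  groups = "αSYN aggregation"),
         reaction("out", c(asyn = -1), 0, 10, "output")))
  tf <- withr::local_tempfile(fileext = ".xml")
  write_sbml_model(m, tf)
  back <- read_sbml_model(tf)$model
  expect_identical(back$metabolites$name[1],
                   "αSYN <aggregation-prone> & sticky")
  expect_identical(back$reactions[[1]]$groups, "αSYN aggregation")

  # truncated stream: parse error, no partial model
  txt <- readLines(tf)
  tf2 <- withr::local_tempfile(fileext = ".xml")
  writeLines(txt[1:(length(txt) %/% 2)], tf2)
  expect_error(read_sbml_model(tf2), "parse error")
  tf3 <- withr::local_tempfile(fileext = ".xml")
  writeLines("<notsbml/>", tf3)
  expect_error(read_sbml_model(tf3), "parse error")
})

test_that("Level 2 kinetic-law bounds are honored, defaults warned about", {
  l2 <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
 <model id="mini">
  <listOfSpecies>
   <species id="A" compartment="cytosol"/>
  </listOfSpecies>
  <listOfReactions>
   <reaction id="A_IN" reversible="false">
    <listOfProducts><speciesReference species="A" stoichiometry="1"/></listOfProducts>
    <kineticLaw>
     <listOfParameters>
      <parameter id="LOWER_BOUND" value="2"/>
      <parameter id="UPPER_BOUND" value="7"/>
     </listOfParameters>
    </kineticLaw>
   </reaction>
   <reaction id="A_OUT" reversible="false">
    <listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants>
   </reaction>
  </listOfReactions>
 </model>
</sbml>'
  tf <- withr::local_tempfile(fileext = ".xml")
  writeLines(l2, tf)
  expect_warning(doc <- read_sbml_model(tf), "default range")
  expect_identical(doc$sbml_level_version, "L2V4")
  r <- doc$model$reactions
  expect_equal(c(r[[1]]$lower_bound, r[[1]]$upper_bound), c(2, 7))
  expect_equal(c(r[[2]]$lower_bound, r[[2]]$upper_bound), c(0, 100))
  # boundary kinds inferred from the sign pattern / IN-OUT suffix convention
  expect_identical(r[[1]]$boundary_kind, "input")
  expect_identical(r[[2]]$boundary_kind, "output")
})

test_that("TSV reaction-table round trip is lossless", {
  models <- c(list(skeleton = make_skeleton_model()),
              micro_fixtures()["chain"],
              list(synthetic = generate_random_network(
                synthetic_spec(5, 8, seed = 3))$model))
  for (nm in names(models)) {
    m <- models[[nm]]
    tf <- withr::local_tempfile(fileext = ".tsv")
    write_reaction_table(m, tf)
    back <- read_reaction_table(tf)
    expect_equal(back$metabolites, m$metabolites, ignore_attr = "row.names")
    expect_true(isTRUE(reactions_equal(m, back)), label = nm)
    # stable bytes and stable re-read
    tf2 <- withr::local_tempfile(fileext = ".tsv")
    write_reaction_table(m, tf2)
    expect_identical(readLines(tf), readLines(tf2))
  }
})

test_that("TSV format errors carry line numbers", {
  m <- two_reaction_chain()
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_reaction_table(m, tf)
  lines <- readLines(tf)
  dup <- c(lines, lines[3])          # duplicate the first reaction row
  t2 <- withr::local_tempfile(); writeLines(dup, t2)
  expect_error(read_reaction_table(t2), "line 5.*duplicate")
  bad <- lines
  bad[3] <- sub("\\+1 A", "one A", bad[3])
  t3 <- withr::local_tempfile(); writeLines(bad, t3)
  expect_error(read_reaction_table(t3), "line 3.*unparseable")
})

test_that("suite flux table has the published wide layout", {
  m <- make_skeleton_model()
  suite <- run_objective_suite(m)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_flux_table(suite, tf)
  tab <- utils::read.delim(tf, check.names = FALSE)
  expect_identical(names(tab), c("group", "maxApo", "minApo", "maxDeg",
                                 "minDeg"))
  expect_identical(nrow(tab), 18L)
})
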