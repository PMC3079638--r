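test_that("read_sif parses minimal tab-delimited input", {
  sif <- withr::local_tempfile(lines = "A\tpp\tB", fileext = ".sif")
  attrs <- withr::local_tempfile(
    lines = c("node\tcompartment", "A\tcytosol", "B\tmembrane"),
    fileext = ".tsv")
  net <- read_sif(sif, attrs)
  expect_equal(n_nodes(net), 2L)
  expect_equal(n_edges_simple(net), 1L)
  expect_identical(node_compartments(net)[["A"]], "cytosol")
})

test_that("reversed duplicate interactions collapse to one simple edge", {
  sif <- withr::local_tempfile(lines = c("A pp B", "B pp A"),
                               fileext = ".sif")
  attrs <- withr::local_tempfile(
    lines = c("node\tcompartment", "A\tcytosol", "B\tcytosol"),
    fileext = ".tsv")
  net <- read_sif(sif, attrs)
  expect_equal(n_nodes(net), 2L)
  expect_equal(n_edges_simple(net), 1L)
  expect_equal(n_interactions_raw(net), 2L)
})

test_that("SIF dialect: tab lines keep spaces in names, multi-target expands, single field is isolated", {
  sif <- withr::local_tempfile(
    lines = c("actin polymerization\tpp\tF-actin\tG-actin", "lonely node"),
    fileext = ".sif")
  attrs <- withr::local_tempfile(
    lines = c("node\tcompartment",
              "actin polymerization\tcytoskeleton",
              "F-actin\tcytoskeleton", "G-actin\tcytoskeleton",
              "lonely node\tcytosol"),
    fileext = ".tsv")
  net <- read_sif(sif, attrs)
  expect_equal(n_nodes(net), 4L)
  expect_equal(n_edges_simple(net), 2L)
  expect_equal(unname(degree_sequence(net)[["lonely node"]]), 0L)
})

test_that("read_sif error contract: missing files, malformed lines, attribute conflicts", {
  sif <- withr::local_tempfile(lines = "A\tpp\tB", fileext = ".sif")
  attrs_ok <- withr::local_tempfile(
    lines = c("node\tcompartment", "A\tcytosol", "B\tmembrane"),
    fileext = ".tsv")
  expect_error(read_sif("nope.sif", attrs_ok), "not found")
  expect_error(read_sif(sif, "nope.tsv"), "not found")

  bad_sif <- withr::local_tempfile(lines = c("A\tpp\tB", "A\tpp"),
                                   fileext = ".sif")
  expect_error(read_sif(bad_sif, attrs_ok), "line 2")

  conflict <- withr::local_tempfile(
    lines = c("node\tcompartment", "A\tcytosol", "A\tmembrane",
              "B\tmembrane"),
    fileext = ".tsv")
  expect_error(read_sif(sif, conflict), "conflicting compartment")

  missing <- withr::local_tempfile(
    lines = c("node\tcompartment", "A\tcytosol"), fileext = ".tsv")
  expect_error(read_sif(sif, missing), "absent from attribute")
  net <- read_sif(sif, missing, default_compartment = "cytosol")
  expect_equal(n_nodes(net), 2L)

  weird <- withr::local_tempfile(
    lines = c("node\tcompartment", "A\tflagellum", "B\tmembrane"),
    fileext = ".tsv")
  expect_error(read_sif(sif, weird), "vocabulary")
  net2 <- read_sif(sif, weird, allow_extra_compartments = TRUE)
  expect_true("flagellum" %in% net2$vocabulary)
})

test_that("vocabulary can be declared in the attrs header comment", {
  sif <- withr::local_tempfile(lines = "A\tpp\tB", fileext = ".sif")
  attrs <- withr::local_tempfile(
    lines = c("#compartments: head, tail", "node\tcompartment",
              "A\thead", "B\ttail"),
    fileext = ".tsv")
  net <- read_sif(sif, attrs)
  expect_identical(net$vocabulary, c("head", "tail"))
})

test_that("bundled capacitation-core files load to 17 nodes and 19 simple edges", {
  sif <- system.file("extdata", "capacitation_core.sif", package = "capnet")
  attrs <- system.file("extdata", "capacitation_core_nodes.tsv",
                       package = "capnet")
  net <- read_sif(sif, attrs)
  expect_equal(n_nodes(net), 17L)
  expect_equal(n_edges_simple(net), 19L)
  expect_same_network_view(net, capacitation_core_fixture())
})

test_that("simple_view drops loops, collapses parallels, and is idempotent", {
  net <- signaling_network(
    c("A", "B", "C"),
    data.frame(source = c("A", "A", "B", "A"),
               target = c("A", "B", "A", "C")),
    compartments = c(A = "cytosol", B = "cytosol", C = "membrane"))
  sv <- simple_view(net)
  expect_equal(n_nodes(sv), 3L)
  expect_equal(nrow(sv$interactions), 2L)      # A-B once, A-C
  expect_identical(simple_view(sv), sv)        # idempotence
  expect_equal(n_interactions_raw(net), 4L)    # raw multiset untouched
})

test_that("write/read round-trip preserves the simple view; rewrite is byte-identical", {
  nets <- c(
    list(capacitation_core_fixture(), triangle_net(),
         net_from_edges(character(0), nodes = c("solo1", "solo2"))),
    lapply(1:5, function(s)
      random_test_network(12L, seed = s, loops = TRUE, parallel = TRUE)))
  for (net in nets) {
    sif <- withr::local_tempfile(fileext = ".sif")
    attrs <- withr::local_tempfile(fileext = ".tsv")
    write_sif(net, sif, attrs)
    back <- read_sif(sif, attrs)
    expect_same_network_view(net, back)
    sif2 <- withr::local_tempfile(fileext = ".sif")
    attrs2 <- withr::local_tempfile(fileext = ".tsv")
    write_sif(back, sif2, attrs2)
    expect_identical(readLines(sif2), readLines(sif))
    expect_identical(readLines(attrs2), readLines(attrs))
  }
})

test_that("handshake lemma holds on generated networks", {
  for (s in 1:10) {
    net <- random_test_network(sample(5:25, 1L), seed = s,
                               loops = s %% 2 == 0, parallel = s %% 3 == 0)
    expect_equal(sum(degree_sequence(net)), 2L * n_edges_simple(net))
  }
})

test_that("constructor rejects invalid networks", {
  expect_error(
    signaling_network(data.frame(id = c("A", "A"),
                                 compartment = "cytosol")),
    "duplicate")
  expect_error(
    signaling_network(data.frame(id = "A", compartment = "cytosol"),
                      data.frame(source = "A", target = "B")),
    "endpoint")
  expect_error(
    signaling_network(data.frame(id = "A", compartment = "warp core")),
    "vocabulary")
  expect_error(
    signaling_network(data.frame(id = "", compartment = "cytosol")),
    "non-empty")
})
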