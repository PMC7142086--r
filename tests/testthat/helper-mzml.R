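# Programmatic writer for a minimal-but-valid mzML file, used to exercise
# count_ms2_scans() without shipping binary fixtures.

encode_doubles <- function(x) {
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8L,
                                endian = "little"))
}

mzml_spectrum_xml <- function(index, ms_level, polarity, mz, intensity) {
  pol_param <- switch(polarity,
    "+" = '<cvParam cvRef="MS" accession="MS:1000130" name="positive scan" value=""/>',
    "-" = '<cvParam cvRef="MS" accession="MS:1000129" name="negative scan" value=""/>',
    ""
  )
  type_param <- if (ms_level == 1L) {
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>'
  } else {
    '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>'
  }
  array_xml <- function(data, accession, name) {
    enc <- encode_doubles(data)
    sprintf(paste0(
      '<binaryDataArray encodedLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="%s" name="%s" value=""/>',
      '<binary>%s</binary></binaryDataArray>'),
      nchar(enc), accession, name, enc)
  }
  sprintf(paste0(
    '<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
    '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>%s%s',
    '<binaryDataArrayList count="2">%s%s</binaryDataArrayList></spectrum>'),
    index, index + 1L, length(mz), ms_level, pol_param, type_param,
    array_xml(mz, "MS:1000514", "m/z array"),
    array_xml(intensity, "MS:1000515", "intensity array"))
}

# scans: data frame with columns ms_level, polarity ("+", "-", "none")
write_demo_mzml <- function(path, scans) {
  spectra <- vapply(seq_len(nrow(scans)), function(i) {
    mzml_spectrum_xml(i - 1L, scans$ms_level[i], scans$polarity[i],
                      c(100.1, 200.2), c(1000, 2000))
  }, character(1))
  xml <- c(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<cvList count="1"><cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/></cvList>',
    '<fileDescription><fileContent><cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/></fileContent></fileDescription>',
    '<softwareList count="1"><software id="sw" version="1.0"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value=""/></software></softwareList>',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="ic"><cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/></instrumentConfiguration></instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="dp"><processingMethod order="1" softwareRef="sw"><cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/></processingMethod></dataProcessing></dataProcessingList>',
    '<run id="run1" defaultInstrumentConfigurationRef="ic">',
    sprintf('<spectrumList count="%d" defaultDataProcessingRef="dp">', nrow(scans)),
    spectra,
    '</spectrumList></run></mzML>'
  )
  writeLines(xml, path)
  invisible(path)
}
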