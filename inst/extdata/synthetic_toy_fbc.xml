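<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic desk-scale SBML L3/FBC-v2 fixture (not a published model):
     substrate uptake (<= 8) feeds metabolite A; A converts to B through a
     high-capacity route gated by (thrA and thrB) or a capacity-3 bypass gated
     by bypG; biomass consumes B. -->
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="synthetic_toy" fbc:strict="true">
    <listOfParameters>
      <parameter id="zero" value="0" constant="true"/>
      <parameter id="ub_up" value="8" constant="true"/>
      <parameter id="ub_conv" value="100" constant="true"/>
      <parameter id="ub_byp" value="3" constant="true"/>
      <parameter id="ub_big" value="1000" constant="true"/>
    </listOfParameters>
    <listOfSpecies>
      <species id="M_A" compartment="c" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false"/>
      <species id="M_B" compartment="c" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false"/>
    </listOfSpecies>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="G_thrA" fbc:label="thrA"/>
      <fbc:geneProduct fbc:id="G_thrB" fbc:label="thrB"/>
      <fbc:geneProduct fbc:id="G_bypG" fbc:label="bypG"/>
    </fbc:listOfGeneProducts>
    <listOfReactions>
      <reaction id="R_up" reversible="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="ub_up">
        <listOfProducts>
          <speciesReference species="M_A" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R_conv" reversible="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="ub_conv">
        <listOfReactants>
          <speciesReference species="M_A" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_B" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:and>
            <fbc:geneProductRef fbc:geneProduct="G_thrA"/>
            <fbc:geneProductRef fbc:geneProduct="G_thrB"/>
          </fbc:and>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_byp" reversible="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="ub_byp">
        <listOfReactants>
          <speciesReference species="M_A" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_B" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_bypG"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_biomass" reversible="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="ub_big">
        <listOfReactants>
          <speciesReference species="M_B" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="R_biomass" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
  </model>
</sbml>
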