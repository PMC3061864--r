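<?xml version="1.0" encoding="UTF-8"?>
<!-- three-state sequential photocycle: A -> B -> C, terminal long-lived C -->
<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="4">
  <model id="sequential3">
    <listOfSpecies>
      <species id="A" initialAmount="1"/>
      <species id="B" initialAmount="0"/>
      <species id="C" initialAmount="0"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="k1" value="0.53475935828877"/>
      <parameter id="k2" value="0.028735632183908"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="r1" reversible="false">
        <listOfReactants><speciesReference species="A"/></listOfReactants>
        <listOfProducts><speciesReference species="B"/></listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply><times/><ci>k1</ci><ci>A</ci></apply>
          </math>
        </kineticLaw>
      </reaction>
      <reaction id="r2" reversible="false">
        <listOfReactants><speciesReference species="B"/></listOfReactants>
        <listOfProducts><speciesReference species="C"/></listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply><times/><ci>k2</ci><ci>B</ci></apply>
          </math>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
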