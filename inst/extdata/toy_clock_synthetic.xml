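<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic toy reaction network (NOT a published clock model): six
     species with production/decay kinetics, used to exercise the SBML
     import path. Steady states are analytically known:
     A* = k1/k2 = 2, B* = vB*A*^2/(KB^2+A*^2)/k4 = 1.6,
     C* = 0.9/0.3 = 3, D* = 0.6/0.2 = 3, E* = 0.4/0.4 = 1,
     F* = 0.5/0.25 = 2. -->
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
  <model id="toy_clock_synthetic" timeUnits="hour">
    <listOfCompartments>
      <compartment id="cell" size="1" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="A" compartment="cell" initialConcentration="0.1" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>
      <species id="B" compartment="cell" initialConcentration="0" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>
      <species id="C" compartment="cell" initialConcentration="0" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>
      <species id="D" compartment="cell" initialConcentration="0" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>
      <species id="E" compartment="cell" initialConcentration="0.5" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>
      <species id="F" compartment="cell" initialConcentration="0" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="k1" value="2" constant="true"/>
      <parameter id="k2" value="1" constant="true"/>
      <parameter id="vB" value="1" constant="true"/>
      <parameter id="KB" value="1" constant="true"/>
      <parameter id="k4" value="0.5" constant="true"/>
      <parameter id="kC" value="0.9" constant="true"/>
      <parameter id="dC" value="0.3" constant="true"/>
      <parameter id="kD" value="0.6" constant="true"/>
      <parameter id="dD" value="0.2" constant="true"/>
      <parameter id="kE" value="0.4" constant="true"/>
      <parameter id="dE" value="0.4" constant="true"/>
      <parameter id="kF" value="0.5" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="prodA" reversible="false">
        <listOfProducts>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <ci>k1</ci>
          </math>
        </kineticLaw>
      </reaction>
      <reaction id="degA" reversible="false">
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply><times/><ci>k2</ci><ci>A</ci></apply>
          </math>
        </kineticLaw>
      </reaction>
      <reaction id="prodB" reversible="false">
        <listOfProducts>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply>
              <divide/>
              <apply><times/><ci>vB</ci><apply><power/><ci>A</ci><cn>2</cn></apply></apply>
              <apply><plus/><apply><power/><ci>KB</ci><cn>2</cn></apply><apply><power/><ci>A</ci><cn>2</cn></apply></apply>
            </apply>
          </math>
        </kineticLaw>
      </reaction>
      <reaction id="degB" reversible="false">
        <listOfReactants>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply><times/><ci>k4</ci><ci>B</ci></apply>
          </math>
        </kineticLaw>
      </reaction>
      <reaction id="prodC" reversible="false">
        <listOfProducts>
          <speciesReference species="C" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML"><ci>kC</ci></math>
        </kineticLaw>
      </reaction>
      <reaction id="degC" reversible="false">
        <listOfReactants>
          <speciesReference species="C" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply><times/><ci>dC</ci><ci>C</ci></apply>
          </math>
        </kineticLaw>
      </reaction>
      <reaction id="prodD" reversible="false">
        <listOfProducts>
          <speciesReference species="D" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML"><ci>kD</ci></math>
        </kineticLaw>
      </reaction>
      <reaction id="degD" reversible="false">
        <listOfReactants>
          <speciesReference species="D" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply><times/><ci>dD</ci><ci>D</ci></apply>
          </math>
        </kineticLaw>
      </reaction>
      <reaction id="prodE" reversible="false">
        <listOfProducts>
          <speciesReference species="E" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML"><ci>kE</ci></math>
        </kineticLaw>
      </reaction>
      <reaction id="degE" reversible="false">
        <listOfReactants>
          <speciesReference species="E" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply><times/><ci>dE</ci><ci>E</ci></apply>
          </math>
        </kineticLaw>
      </reaction>
      <reaction id="prodF" reversible="false">
        <listOfProducts>
          <speciesReference species="F" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML"><ci>kF</ci></math>
        </kineticLaw>
      </reaction>
      <reaction id="degF" reversible="false">
        <listOfReactants>
          <speciesReference species="F" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply><times/><ci>dF</ci><ci>F</ci></apply>
          </math>
          <listOfLocalParameters>
            <localParameter id="dF" value="0.25"/>
          </listOfLocalParameters>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
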