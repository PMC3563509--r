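<?xml version="1.0"?>
<!-- Synthetic KGML example (not a real KEGG pathway): a small signalling
     cascade used in documentation and tests. -->
<pathway name="path:syn00900" number="00900" title="synthetic cascade example">
  <entry id="1" name="synL1" type="gene"/>
  <entry id="2" name="synR1 synR2" type="gene"/>
  <entry id="3" name="synK1" type="gene"/>
  <entry id="4" name="synK2" type="gene"/>
  <entry id="5" name="synTF1" type="gene"/>
  <entry id="6" name="synI1" type="gene"/>
  <entry id="7" name="synC1" type="compound"/>
  <entry id="9" type="group">
    <component id="3"/>
    <component id="4"/>
  </entry>
  <relation entry1="1" entry2="2" type="PPrel">
    <subtype name="binding/association" value="---"/>
  </relation>
  <relation entry1="2" entry2="9" type="PPrel">
    <subtype name="activation" value="--&gt;"/>
    <subtype name="phosphorylation" value="+p"/>
  </relation>
  <relation entry1="3" entry2="5" type="PPrel">
    <subtype name="activation" value="--&gt;"/>
  </relation>
  <relation entry1="5" entry2="6" type="GErel">
    <subtype name="expression" value="--&gt;"/>
  </relation>
  <relation entry1="6" entry2="1" type="PPrel">
    <subtype name="inhibition" value="--|"/>
  </relation>
  <relation entry1="2" entry2="7" type="PCrel">
    <subtype name="activation" value="--&gt;"/>
  </relation>
</pathway>
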