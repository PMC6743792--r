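<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic KGML fixture: hand-written demo pathway, not a database export -->
<pathway name="path:syn00001" org="syn" number="00001"
         title="Synthetic demo pathway">
  <entry id="1" name="syn:101" type="gene">
    <graphics name="GENEA, ALIASA" type="rectangle"/>
  </entry>
  <entry id="2" name="syn:102" type="gene">
    <graphics name="GENEB" type="rectangle"/>
  </entry>
  <entry id="3" name="syn:103" type="gene">
    <graphics name="GENEC" type="rectangle"/>
  </entry>
  <entry id="5" name="syn:105" type="gene">
    <graphics name="GENEX" type="rectangle"/>
  </entry>
  <entry id="6" name="syn:106" type="gene">
    <graphics name="GENEY" type="rectangle"/>
  </entry>
  <entry id="7" name="undefined" type="group">
    <component id="5"/>
    <component id="6"/>
  </entry>
  <entry id="8" name="cpd:C00001" type="compound">
    <graphics name="C00001" type="circle"/>
  </entry>
  <relation entry1="1" entry2="2" type="PPrel">
    <subtype name="activation" value="--&gt;"/>
  </relation>
  <relation entry1="2" entry2="3" type="PPrel">
    <subtype name="inhibition" value="--|"/>
  </relation>
  <relation entry1="3" entry2="7" type="PPrel">
    <subtype name="activation" value="--&gt;"/>
  </relation>
  <relation entry1="1" entry2="3" type="PPrel">
    <subtype name="binding/association" value="---"/>
  </relation>
</pathway>
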