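<?xml version="1.0" encoding="UTF-8"?>
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema" elementFormDefault="qualified">
  <xs:simpleType name="numberOrNA">
    <xs:restriction base="xs:string">
      <xs:pattern value="NA|[+-]?([0-9]*\.?[0-9]+([eE][+-]?[0-9]+)?|[0-9]+\.)"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:element name="cooccurrence_results">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="documents">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="document" minOccurs="0" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:attribute name="id" type="xs:string" use="required"/>
                  <xs:attribute name="full_text" type="xs:string" use="required"/>
                  <xs:attribute name="source" type="xs:string"/>
                  <xs:attribute name="url" type="xs:string"/>
                  <xs:attribute name="doi" type="xs:string"/>
                  <xs:attribute name="title" type="xs:string"/>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
        <xs:element name="genes">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="gene" minOccurs="0" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="in_document" minOccurs="0" maxOccurs="unbounded">
                      <xs:complexType>
                        <xs:attribute name="ref" type="xs:string" use="required"/>
                      </xs:complexType>
                    </xs:element>
                  </xs:sequence>
                  <xs:attribute name="id" type="xs:string" use="required"/>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
        <xs:element name="pairs">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="pair" minOccurs="0" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:attribute name="gene_i" type="xs:string" use="required"/>
                  <xs:attribute name="gene_j" type="xs:string" use="required"/>
                  <xs:attribute name="level" use="required">
                    <xs:simpleType>
                      <xs:restriction base="xs:string">
                        <xs:enumeration value="sentence"/>
                        <xs:enumeration value="paragraph"/>
                        <xs:enumeration value="document"/>
                      </xs:restriction>
                    </xs:simpleType>
                  </xs:attribute>
                  <xs:attribute name="n" type="xs:nonNegativeInteger" use="required"/>
                  <xs:attribute name="a_i" type="xs:nonNegativeInteger" use="required"/>
                  <xs:attribute name="a_j" type="xs:nonNegativeInteger" use="required"/>
                  <xs:attribute name="b" type="xs:nonNegativeInteger" use="required"/>
                  <xs:attribute name="p_i" type="numberOrNA" use="required"/>
                  <xs:attribute name="p_j" type="numberOrNA" use="required"/>
                  <xs:attribute name="p_ij" type="numberOrNA" use="required"/>
                  <xs:attribute name="mi" type="numberOrNA" use="required"/>
                  <xs:attribute name="odds_ratio" type="numberOrNA" use="required"/>
                  <xs:attribute name="chi2" type="numberOrNA" use="required"/>
                  <xs:attribute name="p_value" type="numberOrNA" use="required"/>
                  <xs:attribute name="adjusted_p" type="numberOrNA" use="required"/>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
        <xs:element name="networks">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="network" minOccurs="0" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:attribute name="level_tag" type="xs:string" use="required"/>
                  <xs:attribute name="nodes" type="xs:nonNegativeInteger" use="required"/>
                  <xs:attribute name="edges" type="xs:nonNegativeInteger" use="required"/>
                  <xs:attribute name="graphml" type="xs:string" use="required"/>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
    </xs:complexType>
  </xs:element>
</xs:schema>
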